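# Independent intraclass-correlation oracle: explicit two-way ANOVA sums of
# squares by direct summation (no aov, no shared code with the package).
icc_oracle <- function(m, model = c("ICC2", "ICC3")) {
  model <- match.arg(model)
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  row_means <- numeric(n)
  for (i in seq_len(n)) row_means[i] <- sum(m[i, ]) / k
  col_means <- numeric(k)
  for (j in seq_len(k)) col_means[j] <- sum(m[, j]) / n
  ssr <- 0; ssc <- 0; sst <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (row_means[i] - grand)^2
  for (j in seq_len(k)) ssc <- ssc + n * (col_means[j] - grand)^2
  for (i in seq_len(n)) for (j in seq_len(k)) sst <- sst + (m[i, j] - grand)^2
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (model == "ICC2") {
    unname((msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n))
  } else {
    unname((msr - mse) / (msr + (k - 1) * mse))
  }
}
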