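group,structure,role,index,side,mean_x,mean_y,mean_z,sd_x,sd_y,sd_z
control,bladder,organ,1,midline,-0.7,-26.5,-1.4,5.3,2.1,3.5
control,cervix,organ,1,midline,36.4,-55.2,-8.2,12.5,7.6,10.4
control,anorectum,organ,1,midline,27.7,-23.5,-1.1,4.5,6.8,3.2
control,symphysis,bone,1,midline,0.0,0.0,0.0,0.0,0.0,0.0
control,ischial_spine,bone,1,left,55.5,-47.9,-57.5,6.5,3.8,5.4
control,coccyx,bone,1,midline,91.7,-61.8,0.0,6.3,4.3,0.0
control,pvm,origin,1,left,9.3,-34.5,-30.3,4.3,4.3,4.2
control,pvm,origin,3,left,-4.3,-14.0,-16.6,3.5,3.1,4.8
control,pvam,insertion,1,left,5.3,-12.3,-16.2,3.0,3.9,3.5
control,pvam,insertion,2,left,17.4,-11.6,-12.5,3.1,3.7,3.6
control,ppm,insertion,1,left,22.0,-3.6,-1.9,5.0,5.6,2.8
control,pam,insertion,2,left,38.3,1.5,-9.0,6.1,6.8,2.7
control,prm,origin,1,left,-8.5,-14.4,-16.9,3.5,3.2,4.4
control,prm,origin,2,left,2.5,-2.8,-17.0,2.1,1.6,4.4
control,prm,insertion,1,left,40.3,-6.5,-1.4,6.1,5.1,2.5
control,icm,origin,1,left,52.9,-47.7,-56.4,6.5,3.8,5.4
control,icm,origin,4,left,10.3,-28.2,-30.1,6.0,4.1,4.6
control,icm,insertion,1,left,77.1,-52.0,-1.8,7.7,7.1,2.5
control,icm,insertion,2,left,37.9,-21.0,-1.5,5.4,5.2,2.5
control,coc,insertion,1,left,82.4,-59.5,-5.0,7.8,7.4,2.9
control,coc,insertion,2,left,54.9,-46.2,-4.8,7.6,8.0,2.8
case,bladder,organ,1,midline,7.4,-18.5,1.4,8.2,9.4,3.9
case,cervix,organ,1,midline,37.9,-45.0,0.1,11.7,15.8,10.0
case,anorectum,organ,1,midline,35.7,-15.9,0.7,6.9,8.5,4.5
case,symphysis,bone,1,midline,0.0,0.0,0.0,0.0,0.0,0.0
case,ischial_spine,bone,1,left,51.9,-47.0,-56.3,4.2,4.7,4.4
case,coccyx,bone,1,midline,92.2,-62.2,0.0,5.8,3.9,0.0
case,pvm,origin,1,left,13.7,-29.4,-31.2,4.4,5.4,4.5
case,pvm,origin,3,left,0.8,-12.2,-19.0,5.4,3.8,6.4
case,pvam,insertion,1,left,11.3,-4.6,-13.4,5.0,6.6,5.9
case,pvam,insertion,2,left,25.3,-5.2,-10.4,5.7,5.6,5.5
case,ppm,insertion,1,left,36.6,5.2,1.1,8.6,7.2,3.0
case,pam,insertion,2,left,52.6,9.7,-6.8,9.8,7.2,3.0
case,prm,origin,1,left,-7.0,-12.4,-15.7,2.6,4.4,5.5
case,prm,origin,2,left,2.7,-1.8,-15.7,1.9,3.1,5.5
case,prm,insertion,1,left,51.7,-4.7,1.4,8.7,7.8,2.7
case,icm,origin,1,left,51.0,-46.9,-54.9,4.4,4.7,4.4
case,icm,origin,4,left,17.2,-24.4,-30.9,9.2,5.3,4.9
case,icm,insertion,1,left,81.1,-51.3,0.0,7.4,5.9,1.6
case,icm,insertion,2,left,51.8,-18.7,0.8,10.4,8.6,1.7
case,coc,insertion,1,left,81.7,-55.8,-2.6,9.5,7.4,2.0
case,coc,insertion,2,left,60.3,-39.4,-2.2,10.3,9.0,2.2
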