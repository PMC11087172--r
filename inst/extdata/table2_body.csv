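protocol,contrast_resolution,spatial_resolution,acrylic,air,bone,polyethylene,water,scaling_pct,uniformity_hu
Head,0.7,6,102.4,-971.2,831.0,-93.3,-11.6,0.2,5.66
H&N,0.5,6,103.8,-971.4,831.4,-96.8,-11.3,0.2,3.99
Thorax,0.4,5,102.0,-970.3,829.5,-95.6,-12.1,0.5,4.51
Thorax slow,0.7,5,108.8,-978.2,846.5,-93.5,-6.9,0.5,8.17
Breast,0.2,5,101.6,-969.5,830.2,-93.5,-13.5,0.2,5.67
Abdomen,0.4,5,102.3,-973.7,833.1,-95.0,-12.0,0.5,5.83
Abdomen large,1.2,5,92.6,-961.2,762.2,-99.5,-20.3,0.1,6.62
Pelvis,0.4,5,102.7,-975.2,837.0,-94.9,-12.1,0.7,5.66
Pelvis large,1.0,5,92.4,-963.0,764.5,-99.6,-21.1,0.8,7.65
Pediatric head,0.6,6,99.3,-962.6,805.2,-97.7,-12.2,0.1,8.75
Pediatric abdomen,0.3,5,98.8,-965.6,820.0,-95.3,-15.3,0.2,9.79
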