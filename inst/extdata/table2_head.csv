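protocol,contrast_resolution,spatial_resolution,acrylic,air,bone,polyethylene,water,scaling_pct,uniformity_hu
Head,2.5,6,115.8,-999.2,931.3,-100.0,-3.1,0.6,4.05
H&N,2.0,6,117.5,-998.1,931.9,-98.2,-0.92,0.2,5.10
Thorax,2.2,5,117.2,-998.1,931.8,-98.9,-1.2,0.9,4.02
Thorax slow,2.6,5,116.8,-997.5,930.5,-97.6,-0.6,0.6,3.66
Breast,1.4,5,116.5,-997.4,928.1,-97.7,-0.7,0.2,4.98
Abdomen,2.0,5,116.9,-998.6,931.7,-98.7,-1.4,0.2,3.93
Abdomen large,2.6,5,115.2,-999.0,887.2,-98.6,-4.7,0.6,6.05
Pelvis,1.7,5,116.5,-998.9,931.3,-99.8,-2.0,0.5,4.02
Pelvis large,3.3,5,115.1,-999.3,887.2,-98.7,-5.4,0.2,6.05
Pediatric head,1.5,6,117.5,-999.9,938.2,-95.7,-0.2,0.4,4.40
Pediatric abdomen,0.7,5,118.8,-999.1,936.2,-95.4,-0.2,0.7,3.04
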