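roi,kind,energy,median_hu,iqr_hu
proximal_rca,lumen,conventional,425,116.9
proximal_rca,lumen,40,743.5,262
proximal_rca,lumen,55,413.4,130.6
proximal_rca,lumen,70,258.7,80.4
proximal_rca,lumen,85,188.2,57.6
proximal_rca,lumen,100,143.5,45.2
proximal_rca,lumen,115,118.1,38.2
proximal_rca,lumen,130,102,36.8
distal_rca,lumen,conventional,414.9,143.1
distal_rca,lumen,40,606.3,288.4
distal_rca,lumen,55,346,143.3
distal_rca,lumen,70,222.7,79.1
distal_rca,lumen,85,163.9,59.3
distal_rca,lumen,100,130.4,47.1
distal_rca,lumen,115,109.4,45.2
distal_rca,lumen,130,95,44
lm,lumen,conventional,451.1,123
lm,lumen,40,828,252
lm,lumen,55,463.5,128.3
lm,lumen,70,284,69.3
lm,lumen,85,205,50.1
lm,lumen,100,160.1,42.9
lm,lumen,115,131.1,38.2
lm,lumen,130,114.8,38.5
distal_lad,lumen,conventional,292.5,135.8
distal_lad,lumen,40,413,244
distal_lad,lumen,55,236.3,134
distal_lad,lumen,70,160,70.9
distal_lad,lumen,85,119.8,55.5
distal_lad,lumen,100,94.6,52.6
distal_lad,lumen,115,80,48.6
distal_lad,lumen,130,69.5,45.3
distal_lcx,lumen,conventional,337.9,115.5
distal_lcx,lumen,40,496.1,265.6
distal_lcx,lumen,55,279.6,146.4
distal_lcx,lumen,70,185.2,91.5
distal_lcx,lumen,85,139.8,63.8
distal_lcx,lumen,100,116.7,56.7
distal_lcx,lumen,115,99,52.9
distal_lcx,lumen,130,90.7,49
ascending_aorta,lumen,conventional,466,154.1
ascending_aorta,lumen,40,871.9,246.9
ascending_aorta,lumen,55,486,130.6
ascending_aorta,lumen,70,301.4,76.3
ascending_aorta,lumen,85,211.4,52.3
ascending_aorta,lumen,100,161.4,40.8
ascending_aorta,lumen,115,130.6,29.5
ascending_aorta,lumen,130,114.2,27.3
lumen_median,lumen_pooled,conventional,397.4,131.4
lumen_median,lumen_pooled,40,691.8,259.9
lumen_median,lumen_pooled,55,380.1,136.4
lumen_median,lumen_pooled,70,243.2,77.9
lumen_median,lumen_pooled,85,172.6,56.4
lumen_median,lumen_pooled,100,135.9,47.5
lumen_median,lumen_pooled,115,113,42.1
lumen_median,lumen_pooled,130,99,40.1
fat,tissue,conventional,-87.1,28.6
fat,tissue,40,-178,47.6
fat,tissue,55,-124,25.3
fat,tissue,70,-101,19.9
fat,tissue,85,-90,17.3
fat,tissue,100,-85,16.4
fat,tissue,115,-81.2,17.9
fat,tissue,130,-78.5,15.5
muscle,tissue,conventional,103.4,36.8
muscle,tissue,40,163.1,56.9
muscle,tissue,55,108,33.1
muscle,tissue,70,81.8,21.3
muscle,tissue,85,70.5,15.2
muscle,tissue,100,63.1,13.3
muscle,tissue,115,58.4,14.1
muscle,tissue,130,56,13
trabecular_bone,tissue,conventional,201.8,100.1
trabecular_bone,tissue,40,481.6,399.1
trabecular_bone,tissue,55,297.4,318.2
trabecular_bone,tissue,70,208.5,236.5
trabecular_bone,tissue,85,169.6,142.6
trabecular_bone,tissue,100,149,126
trabecular_bone,tissue,115,138,112.5
trabecular_bone,tissue,130,130.6,103
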