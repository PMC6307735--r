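row,glc_brain_mean,glc_brain_sd,glc_heart_mean,glc_heart_sd,ace_brain_mean,ace_brain_sd,ace_heart_mean,ace_heart_sd
Ala C3,12.9,1.5,13.4,2.8,3.6,3.5,1.7,1.0
Lac C3,56.5,8.6,45.7,18.5,12.1,5.6,3.7,2.8
Lac C2,0.9,1.9,0.5,2.8,11.1,5.6,2.4,2.1
Gln C4,1.0,0.9,1.1,0.9,14.6,2.7,5.4,1.9
Glu C4,10.8,4.0,11.6,7.8,17.0,6.3,14.2,4.0
Glu C3,3.8,2.4,13.3,6.6,15.7,4.5,32.6,2.7
Glu C2,5.0,2.1,6.3,5.5,16.7,5.6,21.3,2.6
SUM,90.9,2.3,91.8,4.2,90.8,8.8,81.4,2.8
Glycolysis,55.7,7.6,45.3,16.6,1.0,2.8,1.3,1.3
TCAc,22.4,6.5,33.2,15.7,86.3,11.7,78.4,3.0
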