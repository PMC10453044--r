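line,treatment,daa,stem_wsc_pct_dw,grain_weight_g,replicate
Chara,water_deficit,-10,12.0,,1
Chara,water_deficit,0,18.5,,1
Chara,water_deficit,7,27.0,0.05,1
Chara,water_deficit,12,31.0,0.10,1
Chara,water_deficit,17,16.0,0.28,1
Chara,water_deficit,22,5.7,0.52,1
Chara,water_deficit,27,5.0,0.72,1
Chara,water_deficit,32,4.6,0.87,1
w1,water_deficit,-10,11.5,,1
w1,water_deficit,0,17.8,,1
w1,water_deficit,7,25.0,0.05,1
w1,water_deficit,12,28.5,0.09,1
w1,water_deficit,17,17.5,0.24,1
w1,water_deficit,22,9.5,0.44,1
w1,water_deficit,27,8.3,0.60,1
w1,water_deficit,32,7.6,0.70,1
w2,water_deficit,-10,11.8,,1
w2,water_deficit,0,18.0,,1
w2,water_deficit,7,26.0,0.05,1
w2,water_deficit,12,29.9,0.10,1
w2,water_deficit,17,16.5,0.26,1
w2,water_deficit,22,6.7,0.48,1
w2,water_deficit,27,6.0,0.66,1
w2,water_deficit,32,5.5,0.78,1
w3,water_deficit,-10,11.2,,1
w3,water_deficit,0,17.0,,1
w3,water_deficit,7,23.5,0.04,1
w3,water_deficit,12,26.3,0.08,1
w3,water_deficit,17,18.0,0.20,1
w3,water_deficit,22,11.1,0.35,1
w3,water_deficit,27,10.0,0.47,1
w3,water_deficit,32,9.2,0.56,1
Chara,well_watered,-10,12.0,,1
Chara,well_watered,0,19.0,,1
Chara,well_watered,7,26.0,0.06,1
Chara,well_watered,12,30.0,0.14,1
Chara,well_watered,17,32.0,0.40,1
Chara,well_watered,22,33.5,0.75,1
Chara,well_watered,27,35.0,1.10,1
Chara,well_watered,32,31.0,1.40,1
w1,well_watered,-10,11.5,,1
w1,well_watered,0,18.5,,1
w1,well_watered,7,25.5,0.05,1
w1,well_watered,12,29.5,0.13,1
w1,well_watered,17,31.5,0.36,1
w1,well_watered,22,33.0,0.70,1
w1,well_watered,27,34.5,1.00,1
w1,well_watered,32,30.5,1.30,1
w2,well_watered,-10,11.0,,1
w2,well_watered,0,17.0,,1
w2,well_watered,7,23.0,0.05,1
w2,well_watered,12,26.0,0.12,1
w2,well_watered,17,27.5,0.35,1
w2,well_watered,22,28.8,0.68,1
w2,well_watered,27,29.9,0.98,1
w2,well_watered,32,27.0,1.28,1
w3,well_watered,-10,11.8,,1
w3,well_watered,0,18.8,,1
w3,well_watered,7,25.8,0.06,1
w3,well_watered,12,29.8,0.13,1
w3,well_watered,17,31.8,0.38,1
w3,well_watered,22,33.2,0.72,1
w3,well_watered,27,33.9,1.05,1
w3,well_watered,32,30.2,1.38,1
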