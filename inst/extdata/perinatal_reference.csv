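key,value
fgr_fetuses_total,60
fgr_stillborn,33
aga_fetuses_total,43
aga_stillborn,6
birthweight_fgr_mean,34.9
birthweight_fgr_sd,7.2
birthweight_aga_mean,47.2
birthweight_aga_sd,7.1
placental_fgr_mean,4.5
placental_fgr_sd,1.5
placental_aga_mean,5.6
placental_aga_sd,1.3
net_sample_weight_mean,49.7
net_sample_weight_sd,3.0
d2o_weight_mg,2.22
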