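dataset,variable,printed
optum_5var,female,.070
optum_5var,age,.016
optum_5var,disease_duration,.004
optum_5var,hospitalization,<.001
optum_5var,surgery,<.001
optum_5var,fistula,<.001
optum_5var,stricture,.256
optum_5var,history_fistulizing,<.001
optum_5var,imm_tnf_naive,<.001
optum_5var,n_anti_tnf,<.001
optum_5var,concomitant_imm,.208
optum_5var,concomitant_cs,.081
optum_5var,cost_hospitalization,.0350
optum_5var,cost_surgery,.0035
optum_5var,cost_ed_visit,.1585
optum_5var,cost_total,.0170
optum_3var,female,.151
optum_3var,age,.023
optum_3var,disease_duration,<.001
optum_3var,hospitalization,<.001
optum_3var,surgery,<.001
optum_3var,fistula,<.001
optum_3var,stricture,.732
optum_3var,history_fistulizing,<.001
optum_3var,imm_tnf_naive,<.001
optum_3var,n_anti_tnf,<.001
optum_3var,concomitant_imm,.949
optum_3var,concomitant_cs,.313
optum_3var,cost_hospitalization,.0403
optum_3var,cost_surgery,<.0001
optum_3var,cost_ed_visit,.1520
optum_3var,cost_total,.0156
truven_3var,female,.729
truven_3var,age,.232
truven_3var,disease_duration,<.001
truven_3var,hospitalization,<.001
truven_3var,surgery,<.001
truven_3var,fistula,<.001
truven_3var,stricture,.005
truven_3var,history_fistulizing,<.001
truven_3var,imm_tnf_naive,<.001
truven_3var,n_anti_tnf,<.001
truven_3var,concomitant_imm,.072
truven_3var,concomitant_cs,.721
truven_3var,cost_hospitalization,.0002
truven_3var,cost_surgery,<.0001
truven_3var,cost_ed_visit,.2899
truven_3var,cost_total,<.0001
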