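dataset,variable,level,stratum,count,total,printed_pct
optum_5var,female,yes,high,97,179,54.2
optum_5var,female,yes,intermediate,96,152,63.2
optum_5var,female,yes,low,20,27,74.1
optum_3var,female,yes,high,125,221,56.6
optum_3var,female,yes,low,88,137,64.2
truven_3var,female,yes,high,532,935,56.9
truven_3var,female,yes,low,295,510,57.8
optum_5var,hospitalization,yes,high,41,179,22.9
optum_5var,hospitalization,yes,intermediate,52,152,34.2
optum_5var,hospitalization,yes,low,19,27,70.4
optum_3var,hospitalization,yes,high,49,221,22.2
optum_3var,hospitalization,yes,low,63,137,46.0
truven_3var,hospitalization,yes,high,129,935,13.8
truven_3var,hospitalization,yes,low,147,510,28.8
optum_5var,surgery,yes,high,8,179,4.5
optum_5var,surgery,yes,intermediate,29,152,19.1
optum_5var,surgery,yes,low,14,27,51.9
optum_3var,surgery,yes,high,5,221,2.3
optum_3var,surgery,yes,low,46,137,33.6
truven_3var,surgery,yes,high,34,935,3.6
truven_3var,surgery,yes,low,183,510,35.9
optum_5var,fistula,yes,high,10,179,5.6
optum_5var,fistula,yes,intermediate,40,152,26.3
optum_5var,fistula,yes,low,16,27,59.3
optum_3var,fistula,yes,high,3,221,1.4
optum_3var,fistula,yes,low,63,137,46.0
truven_3var,fistula,yes,high,5,935,0.5
truven_3var,fistula,yes,low,54,510,10.6
optum_5var,stricture,yes,high,0,179,0.0
optum_5var,stricture,yes,intermediate,2,152,1.3
optum_5var,stricture,yes,low,0,27,0.0
optum_3var,stricture,yes,high,1,221,0.5
optum_3var,stricture,yes,low,1,137,0.7
truven_3var,stricture,yes,high,1,935,0.1
truven_3var,stricture,yes,low,6,510,1.2
optum_5var,history_fistulizing,yes,high,15,179,8.4
optum_5var,history_fistulizing,yes,intermediate,59,152,38.8
optum_5var,history_fistulizing,yes,low,21,27,77.8
optum_3var,history_fistulizing,yes,high,4,221,1.8
optum_3var,history_fistulizing,yes,low,91,137,66.4
truven_3var,history_fistulizing,yes,high,36,935,3.9
truven_3var,history_fistulizing,yes,low,323,510,63.3
optum_5var,imm_tnf_naive,yes,high,49,179,27.4
optum_5var,imm_tnf_naive,yes,intermediate,10,152,6.6
optum_5var,imm_tnf_naive,yes,low,0,27,0.0
optum_3var,imm_tnf_naive,yes,high,53,221,24.0
optum_3var,imm_tnf_naive,yes,low,6,137,4.4
truven_3var,imm_tnf_naive,yes,high,254,935,27.2
truven_3var,imm_tnf_naive,yes,low,12,510,2.4
optum_5var,n_anti_tnf,0,high,72,179,40.2
optum_5var,n_anti_tnf,0,intermediate,14,152,9.2
optum_5var,n_anti_tnf,0,low,0,27,0.0
optum_5var,n_anti_tnf,1,high,70,179,39.1
optum_5var,n_anti_tnf,1,intermediate,80,152,52.6
optum_5var,n_anti_tnf,1,low,12,27,44.4
optum_5var,n_anti_tnf,2plus,high,37,179,20.7
optum_5var,n_anti_tnf,2plus,intermediate,58,152,38.2
optum_5var,n_anti_tnf,2plus,low,15,27,55.6
optum_3var,n_anti_tnf,0,high,77,221,34.8
optum_3var,n_anti_tnf,0,low,9,137,6.6
optum_3var,n_anti_tnf,1,high,98,221,44.3
optum_3var,n_anti_tnf,1,low,64,137,46.7
optum_3var,n_anti_tnf,2plus,high,46,221,20.8
optum_3var,n_anti_tnf,2plus,low,64,137,46.7
truven_3var,n_anti_tnf,0,high,376,935,40.2
truven_3var,n_anti_tnf,0,low,24,510,4.7
truven_3var,n_anti_tnf,1,high,403,935,43.1
truven_3var,n_anti_tnf,1,low,303,510,59.4
truven_3var,n_anti_tnf,2plus,high,156,935,16.7
truven_3var,n_anti_tnf,2plus,low,183,510,35.9
optum_5var,concomitant_imm,yes,high,48,179,26.8
optum_5var,concomitant_imm,yes,intermediate,37,152,24.3
optum_5var,concomitant_imm,yes,low,11,27,40.7
optum_3var,concomitant_imm,yes,high,59,221,26.7
optum_3var,concomitant_imm,yes,low,37,137,27.0
truven_3var,concomitant_imm,yes,high,241,935,25.8
truven_3var,concomitant_imm,yes,low,154,510,30.2
optum_5var,concomitant_cs,yes,high,88,179,49.2
optum_5var,concomitant_cs,yes,intermediate,92,152,60.5
optum_5var,concomitant_cs,yes,low,17,27,63.0
optum_3var,concomitant_cs,yes,high,117,221,52.9
optum_3var,concomitant_cs,yes,low,80,137,58.4
truven_3var,concomitant_cs,yes,high,484,935,51.8
truven_3var,concomitant_cs,yes,low,269,510,52.7
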