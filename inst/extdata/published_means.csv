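dataset,variable,stratum,n,mean,sd
optum_5var,age,high,179,46.3,16.8
optum_5var,age,intermediate,152,45.2,14.9
optum_5var,age,low,27,36.9,13.6
optum_3var,age,high,221,46.6,17.0
optum_3var,age,low,137,42.8,13.9
truven_3var,age,high,935,43.8,14.7
truven_3var,age,low,510,42.8,13.7
optum_5var,disease_duration,high,179,3.6,3.7
optum_5var,disease_duration,intermediate,152,4.9,4.1
optum_5var,disease_duration,low,27,5.5,4.7
optum_3var,disease_duration,high,221,3.4,3.4
optum_3var,disease_duration,low,137,5.8,4.5
truven_3var,disease_duration,high,935,3.2,3.0
truven_3var,disease_duration,low,510,5.0,3.7
optum_5var,cost_hospitalization,high,179,8018.2,28677.8
optum_5var,cost_hospitalization,intermediate,152,11642.1,23376.7
optum_5var,cost_hospitalization,low,27,22625.8,42506.3
optum_3var,cost_hospitalization,high,221,8265.7,26690.6
optum_3var,cost_hospitalization,low,137,14518.5,29841.9
truven_3var,cost_hospitalization,high,935,5532.3,19277.7
truven_3var,cost_hospitalization,low,510,10341.8,29943.2
optum_5var,cost_surgery,high,179,354.5,1605.3
optum_5var,cost_surgery,intermediate,152,925.5,2355.6
optum_5var,cost_surgery,low,27,1507.0,2315.8
optum_3var,cost_surgery,high,221,352.8,1514.2
optum_3var,cost_surgery,low,137,1217.9,2593.7
truven_3var,cost_surgery,high,935,378.9,1281.0
truven_3var,cost_surgery,low,510,976.3,2757.8
optum_5var,cost_ed_visit,high,179,1919.1,11042.4
optum_5var,cost_ed_visit,intermediate,152,2579.0,7328.8
optum_5var,cost_ed_visit,low,27,5902.5,15235.1
optum_3var,cost_ed_visit,high,221,1898.9,10157.6
optum_3var,cost_ed_visit,low,137,3468.9,9895.1
truven_3var,cost_ed_visit,high,935,871.2,4399.6
truven_3var,cost_ed_visit,low,510,1126.7,4355.2
optum_5var,cost_total,high,179,12943.0,37738.7
optum_5var,cost_total,intermediate,152,17944.2,26623.0
optum_5var,cost_total,low,27,32391.2,49849.4
optum_3var,cost_total,high,221,13067.3,34676.2
optum_3var,cost_total,low,137,22230.5,34659.6
truven_3var,cost_total,high,935,8842.2,21161.7
truven_3var,cost_total,low,510,14591.8,31776.2
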