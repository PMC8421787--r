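comparison,subject,tp,tn,fp,fn,acc_printed,dice_printed
rs_vs_gm,1,45,32,15,8,77,79.7
rs_vs_gm,2,41,35,17,7,76,77.4
rs_vs_gm,3,39,33,13,15,72,73.6
rs_vs_gm,4,37,30,22,11,67,69.2
rs_vs_gm,5,38,35,15,12,73,73.8
rs_vs_gm,6,42,32,18,8,74,76.4
rs_vs_gm,7,45,26,22,7,71,75.6
rs_vs_gm,8,41,27,21,11,68,71.9
rs_vs_gm,9,39,28,22,11,67,70.3
bh_vs_gm,1,36,31,17,16,67,68.6
bh_vs_gm,2,37,33,19,11,70,71.2
bh_vs_gm,3,36,28,19,17,64,66.7
bh_vs_gm,4,29,28,24,19,57,57.4
bh_vs_gm,5,34,30,20,16,64,65.4
bh_vs_gm,6,35,31,19,15,66,67.3
bh_vs_gm,7,41,24,24,11,65,70.1
bh_vs_gm,8,34,23,25,18,57,61.3
bh_vs_gm,9,38,20,30,12,58,64.4
rs_vs_bh,1,65,9,20,6,74,83.3
rs_vs_bh,2,72,9,13,6,81,88.3
rs_vs_bh,3,59,14,17,10,73,81.4
rs_vs_bh,4,52,17,25,6,69,77
rs_vs_bh,5,56,18,18,8,74,81.2
rs_vs_bh,6,62,11,23,4,73,82.1
rs_vs_bh,7,65,9,22,4,74,83.3
rs_vs_bh,8,62,13,19,6,75,83.2
rs_vs_bh,9,60,10,18,12,70,80
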