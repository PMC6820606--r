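regimen,cycle,metric,geo_mean,pi_lo,pi_hi
1200mg_q3w,cycle1,cmax,403,274,581
1200mg_q3w,cycle1,cmin,85,55,133
1200mg_q3w,cycle1,auc_week,1048,763,1471
1200mg_q3w,steady_state,cmax,610,414,891
1200mg_q3w,steady_state,cmin,194,89,383
1200mg_q3w,steady_state,auc_week,2115,1264,3507
840mg_q2w,cycle1,cmax,281,187,420
840mg_q2w,cycle1,cmin,74,48,116
840mg_q2w,cycle1,auc_week,860,617,1237
840mg_q2w,steady_state,cmax,517,334,801
840mg_q2w,steady_state,cmin,226,118,426
840mg_q2w,steady_state,auc_week,2188,1336,3733
1680mg_q4w,cycle1,cmax,563,379,822
1680mg_q4w,cycle1,cmin,97,58,159
1680mg_q4w,cycle1,auc_week,1288,887,1845
1680mg_q4w,steady_state,cmax,759,514,1106
1680mg_q4w,steady_state,cmin,182,87,369
1680mg_q4w,steady_state,auc_week,2217,1357,3705
20mgkg_q3w,cycle1,cmax,501,378,665
20mgkg_q3w,cycle1,cmin,107,70,149
20mgkg_q3w,cycle1,auc_week,1305,1002,1683
20mgkg_q3w,steady_state,cmax,753,544,1038
20mgkg_q3w,steady_state,cmin,238,115,443
20mgkg_q3w,steady_state,auc_week,2596,1592,4140
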