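review,name,n_records,n_included,n_invited,n_contributed,tp,tn,fp,fn,sensitivity_printed,specificity_printed,consensus_printed,included_consensus_printed,title_only_pct,indiv_sens_pct,indiv_spec_pct
1,Quarantine,5606,47,123,65,45,3942,1617,2,95.7,70.9,72.02,60,5.7,84.2,82.2
2,IPC Adherence,3367,32,85,36,31,2437,897,1,96.9,73.0,74.96,61,7.2,86.6,84.1
3,Universal Screening,4378,18,104,38,17,3075,1285,1,94.4,70.5,71.34,65,6.8,85.1,89.9
4,Convalescent Plasma,948,12,122,12,12,827,109,0,100.0,88.7,92.19,63,6.6,89.3,90.9
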