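bull,cleavage_rate,ref_cleavage,embryo_dev_rate,ref_embryo_dev,blastocyst_rate,ref_blastocyst
1,48.53,56.56,37.37,47.83,18.14,27.05
2,57.67,51.69,60.48,55.74,34.88,28.81
3,36.13,48.05,3.57,50.00,2.58,24.03
4,34.25,68.97,3.23,53.75,2.17,37.07
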