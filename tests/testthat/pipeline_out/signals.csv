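"experiment_id","session_id","device_id","condition","div","compartment","raw_mean","n_units","n_fields","signal","qc_pass","qc_reasons","config_hash","package_version"
"E01","E01","E01_treated_D01","ctrl",14,"presyn",105.988913070413,40,1,1.00898464794335,TRUE,"","30c974c6","0.1.0"
"E01","E01","E01_treated_D01","ctrl",14,"postsyn",105.503772973246,40,1,0.946604077717585,TRUE,"","30c974c6","0.1.0"
"E01","E01","E01_treated_D02","ctrl",14,"presyn",106.886709035468,40,1,1.01753141306703,TRUE,"","30c974c6","0.1.0"
"E01","E01","E01_treated_D02","ctrl",14,"postsyn",114.350468184035,40,1,1.02597865859614,TRUE,"","30c974c6","0.1.0"
"E01","E01","E01_control_D01","ctrl",14,"presyn",107.125960335753,40,1,1.01980901816736,TRUE,"","30c974c6","0.1.0"
"E01","E01","E01_control_D01","ctrl",14,"postsyn",104.946981057286,40,1,0.941608412792675,TRUE,"","30c974c6","0.1.0"
"E01","E01","E01_control_D02","ctrl",14,"presyn",100.178896167047,40,1,0.953674920822249,TRUE,"","30c974c6","0.1.0"
"E01","E01","E01_control_D02","ctrl",14,"postsyn",121.018843245673,40,1,1.0858088508936,TRUE,"","30c974c6","0.1.0"
"E02","E02","E02_treated_D01","ctrl",14,"presyn",110.700862709845,40,1,0.997065863293108,TRUE,"","30c974c6","0.1.0"
"E02","E02","E02_treated_D01","ctrl",14,"postsyn",104.65208748512,40,1,0.985306772952031,TRUE,"","30c974c6","0.1.0"
"E02","E02","E02_treated_D02","ctrl",14,"presyn",110.314743943588,40,1,0.993588150187824,TRUE,"","30c974c6","0.1.0"
"E02","E02","E02_treated_D02","ctrl",14,"postsyn",113.296970248746,40,1,1.06669895291775,TRUE,"","30c974c6","0.1.0"
"E02","E02","E02_control_D01","ctrl",14,"presyn",111.56792777472,40,1,1.00487538669047,TRUE,"","30c974c6","0.1.0"
"E02","E02","E02_control_D01","ctrl",14,"postsyn",105.221094307698,40,1,0.990664012254316,TRUE,"","30c974c6","0.1.0"
"E02","E02","E02_control_D02","ctrl",14,"presyn",111.52298565357,40,1,1.0044705998286,TRUE,"","30c974c6","0.1.0"
"E02","E02","E02_control_D02","ctrl",14,"postsyn",101.680626854746,40,1,0.957330261875901,TRUE,"","30c974c6","0.1.0"
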