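"condition","div","pair","mean_tes","sem_tes","n_experiments","config_hash","package_version"
"hOlig",14,"presyn_postsyn",0.0378321772235236,0.00831748366758346,2,"61df26d7","0.1.0"
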