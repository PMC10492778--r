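"experiment_id","condition","div","pair","target_excess","source_mean_excess","n_source_experiments","tes","config_hash","package_version"
"E01","ctrl",14,"presyn_postsyn",0,1,NA,0,"30c974c6","0.1.0"
"E02","ctrl",14,"presyn_postsyn",0,1,NA,0,"30c974c6","0.1.0"
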