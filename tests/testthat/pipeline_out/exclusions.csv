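"device_id","compartment","qc_reasons","config_hash","package_version"
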