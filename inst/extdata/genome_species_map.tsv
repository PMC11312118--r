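genome_id	species	surrogate
GCA_019702695.1_Acarterae	Amphidinium carterae	FALSE
GCA_019702695.1_Acarterae	Alexandrium tamutum	TRUE
GCA_019693525.1_Cfusiformis	Cylindrotheca closterium	TRUE
GCA_006384855.1_Tstriata	Tetraselmis suecica	TRUE
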