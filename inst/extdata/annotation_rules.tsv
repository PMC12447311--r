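field	pattern	flag
keywords	(^|;)Membrane($|;)	is_membrane
location	Cell membrane|Plasma membrane	is_membrane
keywords	Growth factor receptor	is_growth_factor_receptor
keywords	Neurotrophic receptor	is_neurotrophic_receptor
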