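chrom	anchored_contigs	size_bp
Ro01	19	34302027
Ro02	19	40757823
Ro03	30	43767452
Ro04	30	38746748
Ro05	25	41095993
Ro06	37	50854034
Ro07	75	41277220
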