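# Lipid reference standards: adducted m/z, CCS and MSMS fragment values as
# printed for the standard mixture. The PI 33:1 entry stores the printed
# water-loss protonated m/z verbatim (not re-derived from composition).
name	shorthand	adduct	mz	charge	reference_ccs	fragments
TG 54:3	TG 54:3	+Na	907.79	1	335.8	603.55;339.29;265.26
PI 33:1	PI 33:1	+H-H2O	822.62	1	318.2
DG 14:1/14:1	DG 28:2	+H	509.42	1	243.3
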