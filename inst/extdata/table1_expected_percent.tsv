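genotype	assay	percent
N2	H5	7
mes-2(bn11)	H5	9
mes-4(bn67)	H5	71
mes-4(bn85)	H5	65
N2	H3K4me2	0
mes-2(bn11)	H3K4me2	3
mes-4(bn67)	H3K4me2	71
mes-4(bn85)	H3K4me2	78
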