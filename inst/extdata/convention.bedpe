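locus	1000	1001	locus	1999	2000	sv_demo_001	0	+	-	DEL	case
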