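category	key	value
stack	AU.AU	-0.93
stack	AU.UA	-1.1
stack	AU.CG	-2.24
stack	AU.GC	-2.08
stack	AU.GU	-0.55
stack	AU.UG	-1.36
stack	UA.AU	-1.33
stack	UA.UA	-0.93
stack	UA.CG	-2.35
stack	UA.GC	-2.11
stack	UA.GU	-1.27
stack	UA.UG	-1
stack	CG.AU	-2.11
stack	CG.UA	-2.08
stack	CG.CG	-3.26
stack	CG.GC	-2.36
stack	CG.GU	-1.41
stack	CG.UG	-2.11
stack	GC.AU	-2.35
stack	GC.UA	-2.24
stack	GC.CG	-3.42
stack	GC.GC	-3.26
stack	GC.GU	-1.53
stack	GC.UG	-2.51
stack	GU.AU	-1
stack	GU.UA	-1.36
stack	GU.CG	-2.51
stack	GU.GC	-2.11
stack	GU.GU	-0.5
stack	GU.UG	1.29
stack	UG.AU	-1.27
stack	UG.UA	-0.55
stack	UG.CG	-1.53
stack	UG.GC	-1.41
stack	UG.GU	-0.3
stack	UG.UG	-0.5
hairpin	3	5.4
hairpin	4	5.6
hairpin	5	5.7
hairpin	6	5.4
hairpin	7	6
hairpin	8	5.5
hairpin	9	6.4
hairpin	10	6.51
hairpin	11	6.62
hairpin	12	6.71
hairpin	13	6.8
hairpin	14	6.88
hairpin	15	6.95
hairpin	16	7.02
hairpin	17	7.09
hairpin	18	7.15
hairpin	19	7.21
hairpin	20	7.26
hairpin	21	7.32
hairpin	22	7.37
hairpin	23	7.41
hairpin	24	7.46
hairpin	25	7.5
hairpin	26	7.55
hairpin	27	7.59
hairpin	28	7.63
hairpin	29	7.66
hairpin	30	7.7
bulge	1	3.8
bulge	2	2.8
bulge	3	3.2
bulge	4	3.6
bulge	5	4
bulge	6	4.4
bulge	7	4.57
bulge	8	4.71
bulge	9	4.84
bulge	10	4.95
bulge	11	5.05
bulge	12	5.15
bulge	13	5.24
bulge	14	5.32
bulge	15	5.39
bulge	16	5.46
bulge	17	5.52
bulge	18	5.59
bulge	19	5.64
bulge	20	5.7
bulge	21	5.75
bulge	22	5.8
bulge	23	5.85
bulge	24	5.9
bulge	25	5.94
bulge	26	5.98
bulge	27	6.02
bulge	28	6.06
bulge	29	6.1
bulge	30	6.14
internal	2	0.8
internal	3	1.3
internal	4	1.7
internal	5	1.8
internal	6	2
internal	7	2.17
internal	8	2.31
internal	9	2.44
internal	10	2.55
internal	11	2.65
internal	12	2.75
internal	13	2.84
internal	14	2.92
internal	15	2.99
internal	16	3.06
internal	17	3.12
internal	18	3.19
internal	19	3.24
internal	20	3.3
internal	21	3.35
internal	22	3.4
internal	23	3.45
internal	24	3.5
internal	25	3.54
internal	26	3.58
internal	27	3.62
internal	28	3.66
internal	29	3.7
internal	30	3.74
multiloop	a	3.4
multiloop	b	0.4
multiloop	c	0.1
misc	duplex_init	4.09
misc	lxc	1.08
misc	max_loop	30
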