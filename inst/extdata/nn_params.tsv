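param	key1	key2	value
stack	CG	CG	-3.3
stack	CG	GC	-3.4
stack	CG	AU	-2.1
stack	CG	UA	-2.1
stack	CG	GU	-1.4
stack	CG	UG	-2.1
stack	GC	CG	-3.4
stack	GC	GC	-3.3
stack	GC	AU	-2.2
stack	GC	UA	-2.4
stack	GC	GU	-1.5
stack	GC	UG	-2.5
stack	AU	CG	-2.4
stack	AU	GC	-2.1
stack	AU	AU	-1.1
stack	AU	UA	-0.9
stack	AU	GU	-0.6
stack	AU	UG	-1.4
stack	UA	CG	-2.1
stack	UA	GC	-2.1
stack	UA	AU	-1.3
stack	UA	UA	-1.1
stack	UA	GU	-1.0
stack	UA	UG	-1.3
stack	GU	CG	-2.5
stack	GU	GC	-2.1
stack	GU	AU	-1.4
stack	GU	UA	-1.3
stack	GU	GU	-0.5
stack	GU	UG	-0.4
stack	UG	CG	-1.5
stack	UG	GC	-1.4
stack	UG	AU	-0.6
stack	UG	UA	-1.0
stack	UG	GU	0.3
stack	UG	UG	-0.5
hairpin	init	.	3.5
hairpin	per_nt	.	0.25
internal	init	.	1.8
internal	per_nt	.	0.35
multi	init	.	3.4
multi	per_branch	.	0.4
multi	per_nt	.	0.1
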