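gene	kind	variety	comment
4241	f	IQ	C
4241	f	CV	C
4260	p	CV	C, SI (37 nt), E
4262	p	IQ	False PAV
4262	p	CV	False PAV
4278	p	CV	C, I (partial)
4288	p	IQ	False PAV
4288	p	CV	False PAV
4289	f	IQ	C, SI (3 kb)
4289	p	CV	C, I
4290	f	IQ	C, SI (3 kb)
4291	f	IQ	C, SI (3 kb)
4291	p	PI	SI (744 nt)
4292	f	IQ	C, SI (3 kb)
4292	p	CV	C, E (partial), I (partial)
4292	f	PI	C, SI (744 nt)
4293	f	IQ	C, SI (3 kb)
4293	f	PI	C, SI (744 nt)
4294	f	CV	C, SI (3 kb)
4294	f	PI	C, SI (744 nt)
4295	f	CV	C, SI (3 kb)
4295	f	PI	C, SI (744 nt)
4299	p	IQ	I
4299	p	CV	I
4299	p	PI	I
4317	p	PI	False PAV
4318	f	CV	C
4319	f	CV	C
4319	f	PI	C
4320	f	CV	CC
4320	f	PI	C
4321	f	CV	C
4321	f	PI	C
4322	f	CV	C
4322	f	PI	C
4322	f	IQ	Not yet confirmed
4323	f	CV	C
4324	p	IQ	C, E (partial)
4324	f	CV	C
4324	f	PI	C
4326	f	IQ	C, SI (5.8 kb)
4326	f	CV	C, SI (6 kb)
4331	f	PI	C
5453	p	IQ	C, SI (225 bp)
5453	p	CV	C
14632	p	CV	C, E, I, SI (39 bp)
14633	f	IQ	C, SI (7.5 kb)
14633	f	PI	C, SI (7.5 kb)
14634	f	IQ	C, SI (7.5 kb)
14634	f	PI	C, SI (7.5 kb)
14635	f	IQ	C, SI (7.5 kb)
14635	f	PI	C, SI (7.5 kb)
15015	f	CV	C, SI (2.6 kb, transposon)
22141	p	IQ	False PAV
22141	p	PI	False PAV
22145	p	IQ	C, E, I, SI (6.5 kb)
22145	p	CV	C, E, I, SI (6.5 kb)
22145	p	PI	C, E, I, SI (6.5 kb)
22153	p	PI	False PAV
22154	p	CV	False PAV
22154	p	PI	False PAV
23276	f	IQ	C, SI (445 bp)
23276	f	PS	C, SI (310 bp)
23277	f	IQ	C, SI (445 bp)
23277	f	PS	C, SI (310 bp)
23278	f	IQ	C, SI (445 bp)
23278	f	PS	C, SI (310 bp)
23577	p	CV	C, E, I
24733	p	CV	C, I, SI (234 bp, transposon)
24737	f	CV	C
24743	p	CV	C, E, I
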