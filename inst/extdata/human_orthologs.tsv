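# Human orthologue labels for the overlapping regulators. Labels marked
# "text"/"figure" are stated in the source narrative or its interaction
# figure; the rest are standard database gene symbols supplied as a
# curated synthetic stand-in for the unavailable supplementary table.
source_species	source_id	target_species	target_id	evidence
worm	Y53C10A.12	human	HSF1	figure
worm	F26D10.3	human	Hsc70	figure
worm	F54D5.8	human	DnaJB5	figure
worm	K01C8.10	human	CCT4	curated-synthetic
worm	C07G2.3	human	CCT5	curated-synthetic
worm	T09B4.10	human	CHIP	figure
worm	Y94H6A.6	human	UBE2H	curated-synthetic
worm	M7.1	human	Ube2D2	figure
worm	C06A1.1	human	p97	figure
worm	F52D10.3	human	YWHAE	curated-synthetic
worm	M117.2	human	YWHAE	curated-synthetic
worm	C39F7.4	human	RAB1A	text
worm	B0361.10	human	YKT6	curated-synthetic
worm	C54H2.5	human	SURF4	curated-synthetic
worm	Y54E2A.12	human	TBC1D20	curated-synthetic
worm	R11A8.4	human	SIRT1	text
worm	C53A5.3	human	HDAC1	text
worm	F02E9.4	human	SIN3B	text
worm	F59F4.1	human	ACOX1	text
worm	ZK256.1	human	ATP2C1	curated-synthetic
worm	W08D2.5	human	ATP13A2	curated-synthetic
worm	Y43F4B.4	human	SEH1L	curated-synthetic
worm	F49E10.5	human	CTBP1	curated-synthetic
worm	K08F8.6	human	MED13	curated-synthetic
worm	T17E9.1	human	TAOK1	curated-synthetic
worm	H18N23.2	human	PPP1R3C	text
worm	T14F9.1	human	ATP6V1H	curated-synthetic
worm	T21E12.4	human	DYNC1H1	curated-synthetic
worm	Y113G7B.18	human	MED17	curated-synthetic
worm	Y116A8C.35	human	U2AF1	curated-synthetic
worm	F56C11.1	human	DUOX1	curated-synthetic
worm	C32E8.10	human	PICALM	text
worm	JC8.10	human	SYNJ1	text
worm	ZK742.1	human	XPO1	curated-synthetic
worm	C05C8.7	human	MPI	curated-synthetic
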