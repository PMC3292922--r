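# Functional class of each overlapping regulator, keyed by canonical worm
# sequence name. The source column records the symbol as printed in the
# curated table; spelling variants there ("sir2.1", "had-1", "fft-2",
# "H18N13.2") are resolved to the canonical genes.
gene	functional_class	source
Y53C10A.12	Heat shock transcription factor	hsf-1
F26D10.3	Molecular chaperones	hsp-1
F54D5.8	Molecular chaperones	dnj-13
K01C8.10	Molecular chaperones	cct-4
C07G2.3	Molecular chaperones	cct-5
T09B4.10	Ubiquitin related	chn-1
Y94H6A.6	Ubiquitin related	ubc-8
M7.1	Ubiquitin related	let-70
C06A1.1	Ubiquitin related	cdc-48.1
R11A8.4	Histone deacetylases	sir2.1 (printed variant of sir-2.1)
C53A5.3	Histone deacetylases	had-1 (printed variant of hda-1)
F02E9.4	Histone deacetylases	sin-3
F52D10.3	Signalling/chaperone	fft-2 (printed variant of ftt-2)
M117.2	Signalling/chaperone	par-5
F49E10.5	Transcriptional cofactor/regulator	ctbp-1
K08F8.6	Transcriptional cofactor/regulator	let-19
Y113G7B.18	Transcriptional cofactor/regulator	mdt-17
Y116A8C.35	Transcriptional cofactor/regulator	uaf-2
Y43F4B.4	Nucleopore/nuclear export	npp-18
ZK742.1	Nucleopore/nuclear export	xpo-1
C39F7.4	Vesicular transport	rab-1
C54H2.5	Vesicular transport	sft-4
Y54E2A.12	Vesicular transport	tbc-20
B0361.10	Vesicular transport	ykt-6
T21E12.4	Vesicular transport	dhc-1
C32E8.10	Endocytosis	unc-11
JC8.10	Endocytosis	unc-26
W08D2.5	Transport ATPase	catp-6
ZK256.1	Transport ATPase	pmr-1
T14F9.1	Transport ATPase	vha-15
T17E9.1	Protein phosphorylation	kin-18
H18N23.2	Protein phosphorylation	H18N13.2 (printed variant of H18N23.2)
F56C11.1	Other cellular processes	bli-3
C05C8.7	Other cellular processes	phi-49
F59F4.1	Other cellular processes	F59F4.1
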