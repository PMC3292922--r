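# Curated catalog of 28 published modifier screens of neurodegenerative
# disease models in worm, yeast and fly. One row per publication, in source
# order. Disease-model codes: P = polyQ (Htt/SCA), S = alpha-synuclein,
# T = tau, SOD = mutant SOD1, Abeta = amyloid-beta 1-42.
study_id	organism	disease_models	construct	screen_type	n_reported	n_orthologues_expected	reference
1	worm	P	Htt-Q0, Q24, Q33, Q35, and Q40	Genome-wide RNAi	186	186	B10
2	worm	SOD	G85R SOD	Genome-wide RNAi	81	81	B11
3	worm	S	WT alpha-synuclein	Genome-wide RNAi	82	82	B9
4	worm	T	Tau P301L and V337M	Genome-wide RNAi	75	75	B14
5	worm	S	WT alpha-synuclein	Hypothesis-driven RNAi	20	20	B65
6	worm	P	Htt-Q150	Candidate genes	12	12	B37
7	worm	S	WT alpha-synuclein	Systematic RNAi screen	11	11	B68
8	worm	P	Htt-Q128	Candidate genes	4	4	B13
9	worm	Abeta	Abeta1-42	Candidate genes	2	2	B69
10	worm	T	Tau P301L and V337M	Forward genetic	2	2	B70
11	worm	T	Tau V337M	Candidate genes	2	2	B71
12	worm	P	Htt-Q32, Q40, Q56, Q79	Candidate genes	2	2	B72
13	worm	P	Htt-Q2 and Q150	Candidate genes	1	1	B12
14	yeast	P and S	Htt-Q20, Htt-Q53, A53T alpha-synuclein	Genome-wide genetic	138	41	B24
15	yeast	S	alpha-synuclein	Selected genetic screen	77	20	B73
16	yeast	Abeta	Abeta1-42	Genome-wide genetic	40	11	B60
17	yeast	P	Htt-Q103	Genome-wide loss-of-function suppressor	30	5	B50
18	yeast	S	WT alpha-synuclein	Genome-wide overexpression	22	7	B58
19	yeast	S	WT alpha-synuclein	Candidate genes	5	1	B59
20	fly	T	Tau V337M	Large-scale genetic	30	14	B74
21	fly	P	Htt-Q128	protein interaction and selected genetic screen	32	34	B75
22	fly	P	SCA1 82Q and Htt-Q128	Selective genetic modifier screen	24	20	B34
23	fly	T	Tau V337M	Large-scale genetic	24	10	B76
24	fly	P	Htt-Q127	Selective genetic modifier screen	10	2	B77
25	fly	P	SCA3trQ78	Genome-wide screen	18	17	B63
26	fly	P	SCA1 30Q and 82Q	Large-scale genetic	17	11	B78
27	fly	P	Htt-Q127	Genome-wide screen	2	1	B79
28	fly	S	A30P and A53T alpha-synuclein	Candidate gene	1	1	B80
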