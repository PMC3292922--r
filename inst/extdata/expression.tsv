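# Neuronal-expression flags of the overlapping regulators, as printed in
# the curated table ("No?" means uncertain negative, "?" unknown).
gene	neuronal_expression	provenance
Y53C10A.12	yes	row 1
F26D10.3	yes	row 2
F54D5.8	?	row 3
K01C8.10	yes	row 4
C07G2.3	?	row 5
T09B4.10	yes	row 6
Y94H6A.6	?	row 7
M7.1	yes	row 8
C06A1.1	Yes	row 9
F52D10.3	yes	row 10
M117.2	yes	row 10
C39F7.4	yes	row 11
B0361.10	?	row 12
C54H2.5	yes	row 13
Y54E2A.12	?	row 14
R11A8.4	Yes	row 15
C53A5.3	No?	row 16
F02E9.4	yes	row 17
F59F4.1	?	row 18
ZK256.1	yes	row 19
W08D2.5	?	row 20
Y43F4B.4	yes	row 21
F49E10.5	?	row 22
K08F8.6	yes	row 23
T17E9.1	yes	row 24
H18N23.2	?	row 25
T14F9.1	Yes	row 26
T21E12.4	Yes	row 27
Y113G7B.18	?	row 28
Y116A8C.35	Yes	row 29
F56C11.1	No	row 30
C32E8.10	Yes	row 31
JC8.10	Yes	row 32
ZK742.1	?	row 33
C05C8.7	No	row 34
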