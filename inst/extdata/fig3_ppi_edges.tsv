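# Binary protein-protein interactions among the chaperone and
# ubiquitin-related overlapping regulators, labelled by human orthologue.
# Four edges are stated in the source text; two are drawn only in the
# source figure (marked figure-derived).
protein_a	protein_b	provenance
CHIP	Ube2D2	text: CHIP (E3) and Ube2D2 (E2) interact directly
CHIP	p97	text: CHIP and p97 interact
CHIP	Hsc70	text: CHIP interacts with and ubiquitinates Hsc70
CHIP	HSF1	text: CHIP interacts with and ubiquitinates HSF1
Hsc70	DnaJB5	figure-derived
Hsc70	HSF1	figure-derived
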