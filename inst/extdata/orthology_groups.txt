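# Orthology groups transcribed from the curated cross-species projections.
# ACOX: the acyl-CoA oxidase family — yeast POX1 and fly CG5009 project to
# seven worm genes. FTT: the fly 14-3-3 epsilon gene (CG31196) projects to
# the two worm paralogues ftt-2 and par-5.
ACOX: sce|POX1 dme|CG5009 cel|C48B4.1 cel|F08A8.1 cel|F08A8.2 cel|F08A8.3 cel|F08A8.4 cel|F25C8.1 cel|F59F4.1 hsa|ACOX1
FTT: dme|CG31196 cel|F52D10.3 cel|M117.2 hsa|YWHAE
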