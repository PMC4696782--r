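# PTM templates (curated from the American lobster reference peptide set).
# Columns: mature sequence <TAB> directives
#   sulfo:Y<pos>  sulfated tyrosine, 0-based position on the mature peptide
#   ss:<i>-<j>    disulfide between the i-th and j-th cysteines (1-based)
#   pyroglu_E     N-terminal glutamic acid cyclizes to pyroglutamate
#   amide_Cterm   amidation of a precursor C-terminal fragment ending in G
ESFSAWG	pyroglu_E
EFDEYGHMRF	pyroglu_E;sulfo:Y4
GGGEYDDYGHLRF	sulfo:Y4;sulfo:Y7
GDDITNEELAYDDNLATSEYLRDDNNDYLPEELTEDVTEMSSPEMLSESAAALVGKNSVSFIPRL	sulfo:Y10
AVFDSACKGYYDREFWGKLSRVCWDCENLFRQPGYQDKCSEGCFVTTDFTQCVKALLLNVEEYNELAELVR	ss:1-5,2-4,3-6
QVFDQACKGVYDRNLFKKLNRVCEDCYNLYRKPFIVTTCRQNCFEGDTFPRCVMDLGLDLELFLEFRDMIK	ss:1-5,2-4,3-6
AANKVSVCIKNCAQCKIMYHDHFKGGLCADLCVQSGGKFIPDCGRPQTLIPFFLQRLE	ss:1-2,3-4,5-6
ATFTSMCIRNCGQCKEMYGDYFHGQACAESCIMTQGISIPDCNNPATFNRFLKRFI	ss:1-2,3-4,5-6
GLSAECCRKVCTVSELVGYCY	ss:1-3
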