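# Peptide family motif library.
# Columns: family <TAB> anchor(Cterm|Nterm|full) <TAB> pattern <TAB> requires_amidation
# Order is the classification precedence: full-sequence motifs first so that
# e.g. myosuppressin (...VFLRFamide) is not absorbed by the FLRFamide
# C-terminal motif, and FLRFamide before sulfakinin so that ...YLRFamide
# peptides resolve to FLRFamide while ...GHLRFamide falls through to the
# sulfakinin motif.
myosuppressin	full	QDLDHVFLRF	TRUE
orcokinin	Nterm	NFDEIDRS	FALSE
AST-A	Cterm	[YF].FG[LI]	TRUE
FLRFamide	Cterm	[FY]LRF	TRUE
sulfakinin	Cterm	[HY][LM]RF	TRUE
leucokinin	Cterm	[FW].{1,2}W[GA]	TRUE
pyrokinin	Cterm	PR[LP]	TRUE
GSEFLamide	Cterm	GSEFL	TRUE
SIFamide	Cterm	SIF	TRUE
TRP	Cterm	FLGMR	TRUE
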