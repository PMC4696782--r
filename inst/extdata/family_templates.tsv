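# Exact-structure family assignments for peptide families recognized by
# whole-sequence identity rather than a short terminal motif (curated for
# the American lobster reference set; structures in conventional notation).
# Columns: structure <TAB> family
pQITFSRSWVPQa	ACP
pQIRYHQCYFNPISCF	AST-C
SYWKQCAFNAVSCFa	AST-C
DECSLTPVIHILSYPGCVSKPIPSFACQGRCTSYVQVSGSKLWQTERSCMCCQESGEREASVVLNCPKVRKGEPTRRKILTRAPIDCMCRPCTDVXEEGTVLAQEIANFIHDSPMGNVPFLK	bursicon-alpha
RRYDLECETLPSTIHVAKEEFDEAGRVERTCEEDLAVNKCEGACVSKVQPSVNTPSGFLKDCRCCRETHLRAREVTLTHCYDADGNRLTGDRGTLXVIKLREPADCQCFKCGDSTR	bursicon-beta
HRVLKGGCLNYGHSCLGAHa	CCHamide
SCSQFGHSCFGAHa	CCHamide
pQTFQYSRGWTNa	corazonin
PFCNAFTGCa	CCAP
AVFDSACKGYYDREFWGKLSRVCWDCENLFRQPGYQDKCSEGCFVTTDFTQCVKALLLNVEEYNELAELVRa	CHH
pQVFDQACKGVYDRNLFKKLNRVCEDCYNLYRKPFIVTTCRQNCFEGDTFPRCVMDLGLDLELFLEFRDMIKa	CHH
QVFDQACKGVYDRNLFKKLDRVCEDCYNLYRKPFVATTCR+	CHH
+ENCYSNRVFRQCLDDLLMIDVIDEYVSNVQMVa	CHH
RSVEGVSRMEKLLSSSNSPSSTPLGFLSQDHSVN	CPRP
RSWLIDGDEDLQLSQYHSLN	CPRP
RSVEGVSRMEKLLSSISPSSTPLGFLSQDHSVN	CPRP
GLDLGLGRGFSGSQAAKHLMGLAAANFAGGPa	DH31
ASGLSLSIDASMKVLREALYMEIIRKKQRQQMQRAQHNQKLLNSIa	DH44
AANKVSVCIKNCAQCKIMYHDHFKGGLCADLCVQSGGKFIPDCGRPQTLIPFFLQRLE	EH
ATFTSMCIRNCGQCKEMYGDYFHGQACAESCIMTQGISIPDCNNPATFNRFLKRFI	EH
LCGWRLANKLNLVCKGVYNNPGSTGNYLFYRS	ILP
GLSAECCRKVCTVSELVGYCY	ILP
CFITNCPPGa	intocin
APRCNQGGNRLPANNCKYGTVVDWCGGSVCAKGPGEACGGEWSENGECGAGTYCSCGYCNGCSANLECWFGSYC	neuroparsin
ARPDNSAADTLQAIHEAAMAGILGSAEVQYPNRPSMFKSPVELRQYLDALNAYYAIAGRPRFa	NPF
+GFN	orcokinin
NSELINSILGLPKVMNDAa	PDH
RYLPT	proctolin
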