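# Curated reference set: mature neuropeptide structures predicted for the
# American lobster (Homarus americanus) from neural-transcriptome precursor
# mining. Conventional notation: pQ/pE = N-terminal pyroglutamate, trailing
# "a" = C-terminal amide, Y(SO3H) = sulfated tyrosine, "+" = truncated
# (partial) terminus, X = uncalled residue. Disulfide connectivity is not
# encoded in the notation.
# Columns: family <TAB> structure
ACP	pQITFSRSWVPQa
AST-A	HSNYGFGLa
AST-A	TPGYAFGLa
AST-A	SDLYSFGLa
AST-A	SGSYNFGLa
AST-A	SKLYGFGLa
AST-A	PRNYAFGLa
AST-A	SQMYSFGLa
AST-A	PRDYAFGLa
AST-A	PTAYSFGLa
AST-A	ATSYGFGLa
AST-A	AGRYAFGLa
AST-A	TGPYAFGLa
AST-A	AGHYAFGLa
AST-A	ADPYAFGLa
AST-A	AGQYSFGLa
AST-A	SGVYSFGLa
AST-A	AGPYSFGLa
AST-A	AKYSFGIa
AST-A	SYDFGLa
AST-A	VGPYAFGLa
AST-A	AGPYAFGLa
AST-A	SGPYAFGLa
AST-A	SGPYSFGLa
AST-C	pQIRYHQCYFNPISCF
AST-C	SYWKQCAFNAVSCFa
bursicon-alpha	DECSLTPVIHILSYPGCVSKPIPSFACQGRCTSYVQVSGSKLWQTERSCMCCQESGEREASVVLNCPKVRKGEPTRRKILTRAPIDCMCRPCTDVXEEGTVLAQEIANFIHDSPMGNVPFLK
bursicon-beta	RRYDLECETLPSTIHVAKEEFDEAGRVERTCEEDLAVNKCEGACVSKVQPSVNTPSGFLKDCRCCRETHLRAREVTLTHCYDADGNRLTGDRGTLXVIKLREPADCQCFKCGDSTR
CCHamide	HRVLKGGCLNYGHSCLGAHa
CCHamide	SCSQFGHSCFGAHa
corazonin	pQTFQYSRGWTNa
CCAP	PFCNAFTGCa
CHH	AVFDSACKGYYDREFWGKLSRVCWDCENLFRQPGYQDKCSEGCFVTTDFTQCVKALLLNVEEYNELAELVRa
CHH	pQVFDQACKGVYDRNLFKKLNRVCEDCYNLYRKPFIVTTCRQNCFEGDTFPRCVMDLGLDLELFLEFRDMIKa
CHH	QVFDQACKGVYDRNLFKKLDRVCEDCYNLYRKPFVATTCR+
CHH	+ENCYSNRVFRQCLDDLLMIDVIDEYVSNVQMVa
CPRP	RSVEGVSRMEKLLSSSNSPSSTPLGFLSQDHSVN
CPRP	RSWLIDGDEDLQLSQYHSLN
CPRP	RSVEGVSRMEKLLSSISPSSTPLGFLSQDHSVN
DH31	GLDLGLGRGFSGSQAAKHLMGLAAANFAGGPa
DH44	ASGLSLSIDASMKVLREALYMEIIRKKQRQQMQRAQHNQKLLNSIa
EH	AANKVSVCIKNCAQCKIMYHDHFKGGLCADLCVQSGGKFIPDCGRPQTLIPFFLQRLE
EH	ATFTSMCIRNCGQCKEMYGDYFHGQACAESCIMTQGISIPDCNNPATFNRFLKRFI
FLRFamide	FSHDRNFLRFa
FLRFamide	APSKNFLRFa
FLRFamide	NRNFLRFa
FLRFamide	GYSDRNYLRFa
FLRFamide	DQNRNFLRFa
FLRFamide	GAHKNYLRFa
FLRFamide	SGRNFLRFa
FLRFamide	GNRNFLRFa
FLRFamide	GDRNFLRFa
GSEFLamide	AMGSEFLa
GSEFLamide	AVGSEFLa
ILP	LCGWRLANKLNLVCKGVYNNPGSTGNYLFYRS
ILP	GLSAECCRKVCTVSELVGYCY
intocin	CFITNCPPGa
leucokinin	pQAFHPWGa
leucokinin	ASFNPWGa
leucokinin	NTFAPWGa
leucokinin	pESFSAWGa
leucokinin	TRFSAWAa
leucokinin	TRFSPWAa
leucokinin	PSFSAWAa
leucokinin	pQGFSAWAa
leucokinin	VPFSTWGa
leucokinin	AFSAWAa
leucokinin	TFSAWAa
leucokinin	TFRAWAa
leucokinin	PSFNAW+
myosuppressin	pQDLDHVFLRFa
neuroparsin	APRCNQGGNRLPANNCKYGTVVDWCGGSVCAKGPGEACGGEWSENGECGAGTYCSCGYCNGCSANLECWFGSYC
NPF	ARPDNSAADTLQAIHEAAMAGILGSAEVQYPNRPSMFKSPVELRQYLDALNAYYAIAGRPRFa
orcokinin	+GFN
orcokinin	NFDEIDRSGFGFN
orcokinin	NFDEIDRSGFGFH
orcokinin	NFDEIDRSGFGFV
PDH	NSELINSILGLPKVMNDAa
proctolin	RYLPT
pyrokinin	GDDITNEELAY(SO3H)DDNLATSEYLRDDNNDYLPEELTEDVTEMSSPEMLSESAAALVGKNSVSFIPRLa
pyrokinin	DSEDSSVESRNTKTQASIPRPa
pyrokinin	GDGFAFSPRLa
pyrokinin	GADFAFSPRLa
pyrokinin	SDFAFSPRLa
pyrokinin	SLFSPRLa
pyrokinin	AYFSPRLa
SIFamide	+KPPFNGSIFa
sulfakinin	GGGEY(SO3H)DDY(SO3H)GHLRFa
sulfakinin	pEFDEY(SO3H)GHMRFa
TRP	APSGFLGMRa
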