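id	ymax	y0	tau_class	tau	compartment	provenance
GLU	1	0	custom	1	extracellular	reported
AGE	1	0	signaling	NA	extracellular	default
RAGE	1	0	ligand-receptor	NA	macrophage	default
NADPH	1	0	signaling	NA	macrophage	default
ROS	1	0	signaling	NA	macrophage	default
NFkB	1	0	nfkb	NA	macrophage	default
IL6	1	0	combined	NA	extracellular	reported-class
TNFa	1	0	combined	NA	extracellular	reported-class
IL1b	1	0	combined	NA	extracellular	reported-class
IL1R	1	0	ligand-receptor	NA	macrophage	default
TLR4	1	0	ligand-receptor	NA	macrophage	default
PI3K	1	0	signaling	NA	GEC	default
AKT	1	0	signaling	NA	GEC	default
VEGFAmRNA	1	0	transcription	NA	macrophage	default
VEGFA	1	0	translation	NA	extracellular	default
VEGFR1	1	0	ligand-receptor	NA	GEC	default
VEGFR2	1	0	ligand-receptor	NA	GEC	default
PLCg	1	0	signaling	NA	GEC	default
Ca	1	0	signaling	NA	GEC	default
eNOS	1	0	signaling	NA	GEC	default
NO	1	0	signaling	NA	GEC	default
ONOO	1	0	signaling	NA	GEC	default
RAGEec	1	0	ligand-receptor	NA	GEC	default
NADPHec	1	0	signaling	NA	GEC	default
ROSec	1	0	signaling	NA	GEC	default
NFkBec	1	0	nfkb	NA	GEC	default
pJunction	1	0	signaling	NA	GEC	default
MLCK	1	0	signaling	NA	GEC	default
MLCP	1	0	signaling	NA	GEC	default
MLC	1	0	signaling	NA	GEC	default
pMLC	1	0	custom	400	GEC	reported
RhoRock	1	0	signaling	NA	GEC	default
Actin_s	1	0	signaling	NA	GEC	default
Actin_r	1	0	signaling	NA	GEC	default
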