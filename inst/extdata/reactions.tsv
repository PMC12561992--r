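id	rule	W	n	EC50	provenance
1	GLU => AGE	1	1.4	0.5	reported
2	AGE => RAGE	1	1.4	0.5	inferred
3	RAGE => NADPH	1	1.4	0.5	inferred
4	NADPH => ROS	1	1.4	0.5	inferred
5	IL1b => IL1R	1	1.4	0.5	reported
6	IL1R => NFkB	1	1.4	0.5	inferred
7	IL1R => PI3K	1	1.4	0.5	reported
8	NFkB => VEGFAmRNA	1	1.4	0.5	reported
9	NFkB => IL6	1	1.4	0.5	inferred
10	NFkB => TNFa	1	1.4	0.5	inferred
11	VEGFAmRNA => VEGFA	1	1.4	0.5	reported
12	VEGFA => VEGFR1	1	1.4	0.5	inferred
13	VEGFA => VEGFR2	1	1.4	0.5	reported
14	AGE => RAGEec	1	1.4	0.5	reported
15	RAGEec => NADPHec	1	1.4	0.5	reported
16	NADPHec => ROSec	1	1.4	0.5	reported
17	ROSec => NFkBec	1	1.4	0.5	reported
18	NFkBec => IL1b	1	1.4	0.5	reported
19	VEGFR2 => RhoRock	1	1.4	0.5	reported
20	ONOO => RhoRock	1	1.4	0.5	inferred
21	VEGFR2 => PLCg	1	1.4	0.5	inferred
22	PLCg => Ca	1	1.4	0.5	inferred
23	VEGFR2 => pJunction	1	1.4	0.5	inferred
24	PI3K => AKT	1	1.4	0.5	inferred
25	Ca & AKT => eNOS	1	1.4	0.5	inferred
26	eNOS => NO	1	1.4	0.5	inferred
27	NO & ROSec => ONOO	1	1.4	0.5	inferred
28	Ca & !NO => MLCK	1	1.4	0.5	inferred
29	RhoRock => pMLC	1	1.4	0.5	reported
30	MLCK & MLC => pMLC	1	1.4	0.5	inferred
31	!RhoRock => MLCP	1	1.4	0.5	reported
32	MLCP => MLC	1	1.4	0.5	inferred
33	pMLC => Actin_s	1	1.4	0.5	inferred
34	MLC => Actin_r	1	1.4	0.5	inferred
35	NFkB => IL1b	1	1.4	0.5	inferred
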