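patient_id	antibody_class	sequence	copy_number	source_label
A	IgG	TGVRGQRISQ	9	reference-table
A	IgG	QNPGETSKMN	6	reference-table
A	IgG	KYRWYK	3	reference-table
A	IgM	AVHFPDDLITPGD	2	reference-table
A	IgM	AEPPFEF	2	reference-table
A	IgM	PSKAAYVV	3	reference-table
A	IgM	QDLYSSA	3	reference-table
A	IgM	QDIFSSA	3	reference-table
A	IgM	MSSVMTY	1	reference-table
A	IgM	FQSPK	2	reference-table
A	IgM	ASHQNRPFRQAAS	1	reference-table
B	IgG	FSRRAQQVGAK	3	reference-table
B	IgG	DHNRSMSHNRVSNK	1	reference-table
B	IgG	KGMGHHGNG	1	reference-table
B	IgG	KAYGHHLSAE	2	reference-table
B	IgG	GLGVGHKSYSGYWHSWIFGA	1	reference-table
B	IgG	KSHGHHR	1	reference-table
B	IgG	KSNKCFM	1	reference-table
B	IgG	KQSGHHRSE	1	reference-table
B	IgG	WTRRPYDELIV	1	reference-table
C	IgG	KENGRSPTHS	10	reference-table
C	IgG	GRSNKSG	1	reference-table
C	IgG	SPTHP	5	reference-table
C	IgG	GRRNKSG	1	reference-table
D	IgG	VPWSKPWWTQGHNNHNRHHP	1	reference-table
D	IgG	SNVRSFDNPIANTPWSKTL	2	reference-table
D	IgG	IPLPPPSRPF	2	reference-table
D	IgG	HNTRNWTLPP	1	reference-table
D	IgG	SNVISYPDVGNPWSKQINIVNTTSYNMRP	2	reference-table
D	IgG	LPWSKLSSPSSNVKNYMAIPQLHPHNLHSP	1	reference-table
D	IgG	TLHTTHSPFK	1	reference-table
D	IgG	NYEPVPRGAR	1	reference-table
D	IgG	TDAAPWSKVT	2	reference-table
D	IgG	GKSLHGSHHP	1	reference-table
D	IgG	SNVISFRHAS	1	reference-table
D	IgG	TNVISYTPLY	3	reference-table
D	IgM	QSLDHSSC	5	reference-table
D	IgM	LNPQSPRD	4	reference-table
D	IgM	YSWRAT	4	reference-table
D	IgM	NERSEAR	1	reference-table
D	IgM	HFHHLAVRGRPQGWLGWGTVEPDPTRWGARLVK	1	reference-table
D	IgM	GGRWNR	2	reference-table
D	IgM	PETTDK	2	reference-table
D	IgM	PGHVRGTLGR	2	reference-table
D	IgM	YVDTLSKLRGQSLA	1	reference-table
D	IgM	AVRRPD	4	reference-table
D	IgM	QRLAAGFHQLAETLF	1	reference-table
D	IgM	GRKTELF	1	reference-table
D	IgM	YLASPFE	1	reference-table
D	IgM	FRVARAARTGRMWRLVYPQQVVGLVP	2	reference-table
D	IgM	QIQLSGG	1	reference-table
D	IgM	VKNRGR	1	reference-table
Normal control	IgG	DIRLSAQLSW	1	reference-table
Normal control	IgG	SGYYTYTNGV	1	reference-table
Normal control	IgG	HHGRGLYNFMGK	1	reference-table
Normal control	IgG	RRTDYLLNGDPTVSESS	1	reference-table
Normal control	IgG	APQGYLFKESSTKSE	1	reference-table
Normal control	IgG	NQHLILSVGSIAAAVHRANKEPAT	1	reference-table
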