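# Reference binding-specificity group labels of representative PH domains.
# Group 1: specific, high-affinity Ins(1,3,4,5)P4 binders.
# Group 2: Ins(1,4,5)P3 binders with 4-8-fold weaker affinity.
# Group 3: 3-phosphorylated-species binders incl. Ins(1,3,4)P3.
# Group 4: low affinity, little specificity.
# pdb_ids: structures used for the structural analyses ("-" = none here).
domain	group	pdb_ids
Btk	1	1BTK;1B55
Grp1	1	1FGZ;1FGY;1FHW;1FHX
Gap1m	1	-
Gap1IP4BP	1	-
Vav	1	-
cytohesin-1	1	-
Sos	1	-
ARNO	1	-
TIAM1-N	1	-
PLCdelta1	2	1MAI
beta-Ark	2	1BAK
beta-spectrin	2	1BTN;1MPH;1DRO
DAGKdelta	2	-
RasGAP	2	-
OSBP	2	-
IRS-1	2	-
pleckstrin-N	2	1PLS
Dapp1	3	1FB8;1FAO
Akt	3	-
PDK1	3	-
dynamin	4	1DYN
TIAM1-C	4	-
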