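gene	normalized_score	n_enriched_sgrnas	n_total_sgrnas
TP53	1.0000	5	6
TP53BP1	0.9386	4	6
TRIM37	0.9039	3	6
USP28	0.8895	4	6
P21	0.8858	6	6
CHD8	0.7559	4	6
FBXO42	0.6945	3	6
RNF20	0.6846	3	6
PCDHGC5	0.6665	2	6
TSPY8	0.6604	3	6
RWDD3	0.6395	2	6
UGT1A9	0.6364	2	6
PDSS1	0.6285	2	6
BPIFB4	0.6275	2	6
PCDHAC2	0.6240	3	6
CSNK2A1	0.6218	2	6
GAGE7	0.6201	3	6
WTAP	0.6119	2	6
PRDM11	0.6093	2	6
OR56A1	0.6086	2	6
TBCEL	0.6059	2	6
DNAJC9	0.5997	2	6
NPIPL3	0.5991	3	6
SYDE1	0.5987	2	6
TECPR2	0.5959	2	6
STOML3	0.5683	2	6
DVL3	0.5507	2	6
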