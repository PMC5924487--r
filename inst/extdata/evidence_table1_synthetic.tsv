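# synthetic literature-evidence table for the 19 candidate TF genes
# counts are SYNTHETIC stand-ins (not measured values); they preserve the
# qualitative structure of a PubMed evidence screen: 9 genes exceed 100
# total articles and HIF1A, CREB1 and NFKB1 carry the largest totals.
# column identity: cell_growth_or_angiogenesis = cell_growth + angiogenesis
#                  - cell_growth_plus_angiogenesis
gene	cell_growth_plus_angiogenesis	cell_growth_or_angiogenesis	cell_growth	angiogenesis
ELK3	1	15	2	14
HEY1	7	31	21	17
HIF1A	611	2871	2150	1332
HMGB1	29	620	346	303
HOXB3	1	5	3	3
ID1	24	314	285	53
KLF5	4	36	31	9
UBP1	0	1	0	1
VEZF1	0	2	0	2
ABL1	11	60	48	23
ADNP	0	5	5	0
CREB1	75	946	644	377
ENO1	4	19	17	6
IGFBP1	27	145	139	33
SMARCA4	6	31	29	8
SOX9	18	280	211	87
TAF9	0	4	4	0
WT1	58	460	422	96
NFKB1	662	6181	3967	2876
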