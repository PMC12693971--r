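gene	chrom	pos_hg38	ref	archaic	status
KIF26B	1	245419603	A	G	fixed_af1
NOTO	2	73210883	T	A	fixed_af1
GRM6	5	178994530	G	T	fixed_af1
ADAM18	8	39680099	C	T	fixed_af1
ADAM18	8	39706833	G	A	fixed_af1
DCHS1	11	6633538	C	T	fixed_af1
KNL1	15	40620662	G	A	fixed_af1
KNL1	15	40623442	A	G	fixed_af1
ZNF106	15	42450114	C	T	fixed_af1
SPAG5	17	28592016	G	C	fixed_af1
SPAG5	17	28592759	C	T	fixed_af1
SPAG5	17	28598560	A	G	fixed_af1
SSH2	17	29632016	T	C	fixed_af1
RFNG	17	82049104	G	A	fixed_af1
GREB1L	18	21505418	A	G	fixed_af1
LMNB2	19	2434035	A	T	fixed_af1
C3	19	6685100	G	A	fixed_af1
PLACEHOLDER_19	9	6606647	G	A	fixed_af1
PLACEHOLDER_01	3	3000138	A	G	fixed_af1
PLACEHOLDER_01	3	3000275	A	G	fixed_af1
PLACEHOLDER_02	4	3000412	A	G	fixed_af1
PLACEHOLDER_02	4	3000549	A	G	fixed_af1
PLACEHOLDER_03	5	3000686	A	G	fixed_af1
PLACEHOLDER_04	6	3000823	A	G	fixed_af1
PLACEHOLDER_05	7	3000960	A	G	fixed_af1
PLACEHOLDER_06	10	3001097	A	G	fixed_af1
PLACEHOLDER_07	12	3001234	A	G	fixed_af1
PLACEHOLDER_08	13	3001371	A	G	fixed_af1
PLACEHOLDER_09	14	3001508	A	G	fixed_af1
PLACEHOLDER_10	16	3001645	A	G	fixed_af1
PLACEHOLDER_11	20	3001782	A	G	fixed_af1
PLACEHOLDER_12	22	3001919	A	G	fixed_af1
PLACEHOLDER_13	2	3002056	A	G	fixed_af1
PLACEHOLDER_14	3	3002193	A	G	fixed_af1
PLACEHOLDER_15	4	3002330	A	G	fixed_af1
PLACEHOLDER_16	6	3002467	A	G	fixed_af1
PLACEHOLDER_17	7	3002604	A	G	fixed_af1
PLACEHOLDER_18	10	3002741	A	G	fixed_af1
C1orf159	1	1091245	A	G	fixed_af1
DNHD1	11	6534188	A	G	fixed_af1
DNMT3L	21	44251169	A	G	fixed_af1
TBC1D3	17	38202786	A	G	fixed_af1
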