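gene	chrom	start	ref	alt	aa_substitution	criteria
hamp	1	14423573	A	T	N81Y	ES, AS, PD
fga-like	2	1113231	G	T	R537Q; A574S	Sma-E137 (GR, OUT) gene; 13831_88 (OUT farm) < 500 kb; PD; AS
arhgap42	3	7539292	C	A	T632K; T793N	1916_69 (OUT) gene; GR-OST
vtna	3	15402438	G	T	D185E	Sma-USC214 (GR, PD) < 500 kb; PD
paxbp1	4	10752137	G	A	P47L	ES; GR-OFS
cmtm3	5	10463315	T	C	K83R	5986_20 (OUT farm) < 500 kb; ES
igf1rb	5	22614990	A	G	Y980H	Sma-USC7 (GR) gene; GR-OFS
hmox	8	13184347	A	G	T81A	7560_71 (OUT farm) and 7235_80 (OUT farm) < 500 kb; PD; AS; ES
ciart	10	12731534	A	G	N271S	SmaUSC-E29 (OUT) gene; AS; ES; GR-OFS
slc12a3	10	24208615	G	C	D38N; C938S	ES; OR-OFS
frs2	10	25869534	G	A	A124T; A290P	SmaUSC-E7 (GR, OUT) gene;
igfbp2	14	4200650	G	A	P264S	PD; GR-OFS;
ccnb1	16	2499469	C	T	A390V	Sma-USC146 (OUT) < 500 kb; ES
fgfr3	17	2378412	G	C	P45R	Sma-USC30 (GR, PD) < 500 kb; ES
hbaD	18	9550815	G	A	A44T; V78I	GR-OFS
aqp8b	19	11066153	G	T	Q36H	AS, ES; OR-OFS;
hgs	19	13543170	C	A	P726T	SmaSNP_298 (GR, PD) < 500 kb; ES
sstr3	19	19851767	C	T	S414L	SmaSNP_192 (GR) < 500 kb, ES; GR-OFS;
tshr	20	5830531	T	A	L339Q	Sma-USC273 (GR, PD) < 500 kb; AS
myb	20	10176750	C	T	C4Y	Sma-USC38 (OUT, PD) < 500 kb; AS
vipr1b	21	2341297	T	C	N2D	Sma-E112 (OUT) < 500 kb; Sma-USC91 (GR; VHSV) < 500 kb; ES
eya3	22	5576482	G	T	R22L; S230G	ES; GR-OFS;
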