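##fileformat=VCFv4.2
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##INFO=<ID=EFFECT,Number=1,Type=String,Description="Effect class">
##INFO=<ID=ORIGIN,Number=1,Type=String,Description="somatic or germline">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	TUMOR	NORMAL
chr1	100100	.	C	T	.	.	GENE=gene01;EFFECT=missense;ORIGIN=somatic	GT:AD	./.:60,15	./.:70,0
chr1	200200	.	C	T	.	.	GENE=gene02;EFFECT=nonsense;ORIGIN=somatic	GT:AD	./.:60,9	./.:70,0
chr1	300300	.	C	T	.	.	GENE=gene03;EFFECT=frameshift;ORIGIN=somatic	GT:AD	./.:55,20	./.:60,3
chr1	400400	.	C	T	.	.	GENE=gene04;EFFECT=splice;ORIGIN=somatic	GT:AD	./.:30,15	./.:70,0
chr1	500500	.	C	T	.	.	GENE=gene05;EFFECT=missense;ORIGIN=somatic	GT:AD	./.:60,20	./.:40,1
chr2	1500100	.	C	T	.	.	GENE=gene06;EFFECT=nonsense;ORIGIN=somatic	GT:AD	./.:60,20	./.:70,0
chr3	100100	.	C	T	.	.	GENE=gene07;EFFECT=frameshift;ORIGIN=somatic	GT:AD	./.:40,10	./.:48,2
chr3	200200	.	C	T	.	.	GENE=gene08;EFFECT=splice;ORIGIN=somatic	GT:AD	./.:35,9	./.:70,0
chr2	1501000	.	C	T	.	.	GENE=gene09;EFFECT=missense;ORIGIN=somatic	GT:AD	./.:50,20	./.:55,5
chr2	1505999	.	C	T	.	.	GENE=gene10;EFFECT=nonsense;ORIGIN=somatic	GT:AD	./.:20,5	./.:25,4
chr4	100100	.	C	T	.	.	GENE=gene11;EFFECT=frameshift;ORIGIN=somatic	GT:AD	./.:100,30	./.:120,0
chr4	200200	.	C	T	.	.	GENE=gene12;EFFECT=splice;ORIGIN=somatic	GT:AD	./.:45,40	./.:90,0
chr4	300300	.	C	T	.	.	GENE=gene13;EFFECT=missense;ORIGIN=somatic	GT:AD	./.:39,10	./.:80,1
chr4	400400	.	C	T	.	.	GENE=gene14;EFFECT=nonsense;ORIGIN=somatic	GT:AD	./.:41,10	./.:80,1
chr5	100100	.	C	T	.	.	GENE=gene15;EFFECT=frameshift;ORIGIN=somatic	GT:AD	./.:90,10	./.:50,0
chr5	200200	.	C	T	.	.	GENE=gene16;EFFECT=splice;ORIGIN=somatic	GT:AD	./.:90,11	./.:48,2
chr5	300300	.	C	T	.	.	GENE=gene17;EFFECT=missense;ORIGIN=somatic	GT:AD	./.:90,10	./.:50,3
chr6	100100	.	C	T	.	.	GENE=gene18;EFFECT=nonsense;ORIGIN=somatic	GT:AD	./.:300,9	./.:300,0
chr6	200200	.	C	T	.	.	GENE=gene19;EFFECT=frameshift;ORIGIN=somatic	GT:AD	./.:10,45	./.:200,0
chr2	1506100	.	C	T	.	.	GENE=gene20;EFFECT=splice;ORIGIN=somatic	GT:AD	./.:60,20	./.:70,0
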