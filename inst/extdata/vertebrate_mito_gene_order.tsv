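name	kind	strand	start	end
trnF	tRNA	+	1	68
rrnS	rRNA	+	69	1018
trnV	tRNA	+	1019	1090
rrnL	rRNA	+	1091	2757
trnL2	tRNA	+	2758	2831
nad1	PCG	+	2832	3806
trnI	tRNA	+	3807	3877
trnQ	tRNA	-	3878	3948
trnM	tRNA	+	3949	4017
nad2	PCG	+	4018	5063
trnW	tRNA	+	5064	5134
trnA	tRNA	-	5135	5203
trnN	tRNA	-	5204	5276
trnC	tRNA	-	5277	5342
trnY	tRNA	-	5343	5412
cox1	PCG	+	5413	6963
trnS2	tRNA	-	6964	7034
trnD	tRNA	+	7035	7103
cox2	PCG	+	7104	7794
trnK	tRNA	+	7795	7868
atp8	PCG	+	7869	8036
atp6	PCG	+	8037	8720
cox3	PCG	+	8721	9506
trnG	tRNA	+	9507	9575
nad3	PCG	+	9576	9924
trnR	tRNA	+	9925	9993
nad4l	PCG	+	9994	10290
nad4	PCG	+	10291	11671
trnH	tRNA	+	11672	11740
trnS1	tRNA	+	11741	11808
trnL1	tRNA	+	11809	11881
nad5	PCG	+	11882	13720
nad6	PCG	-	13721	14242
trnE	tRNA	-	14243	14311
cob	PCG	+	14312	15452
trnT	tRNA	+	15453	15524
trnP	tRNA	-	15525	15595
CR	CR	+	15596	16502
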