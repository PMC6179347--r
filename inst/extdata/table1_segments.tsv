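id	previous_name	chromosome	host_start	host_end	strand	viral_start	viral_end	length_bp	disruptive_mutations	dist_left_gene	dist_right_gene
d1	JaE1-4	1	5193920	5194407	+	6880	7353	488	NA	43579	7455
d2	JaE1-4	1	5194744	5195008	+	108	359	265	0	44403	6854
d3	JaE1-4	1	5195124	5198055	+	4259	7180	2932	9	44783	3807
d4	NA	2	12120385	12120601	+	6540	6758	217	NA	5419	7312
d5	NA	2	12120644	12121245	-	6539	7184	602	NA	5678	6668
d6	NA	4	18488307	18488450	+	6873	7021	144	NA	8092	1903
d7	NA	4	18488544	18488674	-	6852	6984	131	NA	8329	1679
d8	NA	4	21097520	21097778	-	6952	7196	259	NA	86783	85199
d9	NA	5	6506720	6507050	-	6953	7278	331	NA	8332	7696
d10	JaE7-4	7	8906209	8907980	+	5547	7343	1772	5	27304	18154
d11	JaE7-5/7-6	7	8909007	8920257	-	4817	7341	11251	9	30102	5877
d12	NA	9	16726920	16727025	+	32	137	106	0	5997	1153
d13	NA	10	9099571	9099688	-	2584	2696	118	1	5282	2080
d14	JaE11-2	11	5069912	5072964	+	3580	6416	3053	19	5378	243
d15	JaE11-5	11	11654495	11657114	-	3806	6413	2620	15	2608	4216
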