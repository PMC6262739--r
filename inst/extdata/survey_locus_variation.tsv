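# Per-locus variation summaries from the same published SSR survey:
# repeat motif, observed repeat counts, mutated-motif status, fragment
# length range, and counts of variable sites (SNPs, indels, and repeat
# count variation). Two-region locus mt11151 lists both regions separated
# by "/". Empty indel_lengths means no flanking indel.
species	locus	motif	repeat_counts	mean_ssr_length	mutated_motif	fragment_lengths	mean_fragment_length	n_variable_sites	n_snps	n_indels	indel_lengths
Donatia fascicularis	df14769	CAC	5-7,9,10	22.2	Yes	367-382	374.5	6	5	0
Donatia fascicularis	df123709	AGG	6,7	19.5	No	329-344	336.5	9	8	0
Donatia fascicularis	df124143	TGG	4,7,9	20	No	369-384	375.5	12	11	0
Donatia fascicularis	df126453	CTT	4,7-10,14	27.7	No	315-345	330	4	3	0
Donatia fascicularis	df137861	ACA	6-8	21	Yes	318-324	321	10	8	1	2
Donatia fascicularis	df138027	TTCTGA	1,3-5	18	No	289-313	301	6	5	0
Donatia fascicularis	df142807	CTTTGC	3	18	No	288-301	294.5	9	8	1	13
Donatia fascicularis	df22716	CAAAC	2-5	14	No	329-344	336.5	6	5	0
Donatia fascicularis	df51291	CTT	4,6,7,9-13	27.75	Yes	318-345	331.5	11	8	2	1,8
Donatia fascicularis	df61486	CAAGG	4-6	25	No	289-299	294	6	4	1	1
Donatia fascicularis	df79494	CTCA	2,4,7,9-13,15	36.7	Yes	253-305	279	4	2	1	9
Donatia fascicularis	df80221	GGT	4-9	19.5	No	314-329	321.5	8	7	0
Donatia fascicularis	df80820	TTG	6,8,9	23	No	304-314	309	10	8	1	1
Donatia fascicularis	df91667	ATAG	3,5-10	26.9	No	243-266	254.5	13	8	4	2,2,7,15
Mulguraea tridens	mt10760	AAG	6-9	22.5	No	337-346	341	2	1	0
Mulguraea tridens	mt11151	TGA/TCC	3,6-8,10-13/4-6	26.25/15	Yes	330-363	350.5	19	18	1	3
Mulguraea tridens	mt14700	GAT	6,7,10	23	No	341-353	347	6	4	1	3
Mulguraea tridens	mt16240	GAA	6-11	25.5	Yes	301-316	308.5	7	6	0
Mulguraea tridens	mt16881	ATA	8,11	28.5	No	379,388	383.5	5	4	0
Mulguraea tridens	mt17340	TTGA	3-6	13.5	Yes	358-370	364	3	2	0
Mulguraea tridens	mt17642	GAG	6-9	22.5	Yes	310-319	314.5	6	4	1	3
Mulguraea tridens	mt21753	AGA	4,6,7	17	No	269-287	278.6	5	2	2	6,15
Mulguraea tridens	mt23026	CAT	8,10	27	Yes	369,375	372	7	5	1	3
Mulguraea tridens	mt24277	ATC	10,13,14,17	40.5	No	317-338	327.5	2	1	0
Mulguraea tridens	mt25107	GAA	5,6,8-10,12	25	No	286-307	296	4	3	0
Mulguraea tridens	mt25266	ATG	5,10-14	32.5	Yes	374-401	390.3	15	13	1	6
Mulguraea tridens	mt27365	ATC	5-11	24	No	275-293	284	5	4	0
Mulguraea tridens	mt28267	GAT	6	18	No	385	385	16	16	0
Mulguraea tridens	mt30890	CTT	6,7	19.5	No	210,213	211.5	6	5	0
Mulguraea tridens	mt34724	AAT	6	18	No	257	257	5	5	0
Mulguraea tridens	mt57863	GAA	7,8,10	25	Yes	331-340	335	5	4	0
Oreobolus obtusangulus	oo12746	CAC	6-8,10	23.25	No	315-327	321	7	6	0
Oreobolus obtusangulus	oo14265	CGG	2,6,9	17	Yes	345-366	355.5	5	4	0
Oreobolus obtusangulus	oo16914	TGG	7,8,12	27	Yes	412-418	415	9	8	0
Oreobolus obtusangulus	oo17752	TTC	7-8	22.5	No	313-325	319	9	7	1	9
Oreobolus obtusangulus	oo20129	CGCCTC	3-6	27	No	326-344	335	8	6	1	12
Oreobolus obtusangulus	oo20553	GATTTG	4-6	30	Yes	356-368	362	4	3	0
Oreobolus obtusangulus	oo25879	AACCAA	2-5	21	Yes	334-352	343	4	3	0
Oreobolus obtusangulus	oo34170	GATT	3-6	18	No	307-319	313	7	5	1	4
Oreobolus obtusangulus	oo40886	TTC	4-6,9-12	24.3	Yes	337-364	350.5	5	3	1	3
Oreobolus obtusangulus	oo41307	GAA	12-19	46.5	Yes	324-345	334.5	5	4	0
Oreobolus obtusangulus	oo48962	GAT	7-16,20	36.8	Yes	383-410	396.5	8	6	2	3,12
Oreobolus obtusangulus	oo56658	CAT	10-14	36	Yes	319-331	325	8	7	0
Oreobolus obtusangulus	oo59128	TTCTT	4-6	20	No	301-313	307	11	9	1	11
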