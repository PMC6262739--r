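# Per-locus allele counts and rare-allele counts (alleles occurring exactly
# once) under the three coding schemes, from the same published SSR survey.
# mt11151 contains two repeat regions and appears as two sub-loci
# (mt11151a/mt11151b) in the SSR-length scheme only; NA marks columns not
# applicable to a sub-locus.
species	locus	na_ssr	na_frag	na_seq	rare_ssr	rare_frag	rare_seq
Donatia fascicularis	df14769	4	4	13	1	1	3
Donatia fascicularis	df123709	2	2	11	0	0	3
Donatia fascicularis	df124143	2	2	6	0	0	0
Donatia fascicularis	df126453	9	9	11	0	0	1
Donatia fascicularis	df137861	3	4	12	1	1	5
Donatia fascicularis	df138027	4	4	8	0	0	0
Donatia fascicularis	df142807	1	2	8	0	0	0
Donatia fascicularis	df22716	4	4	8	1	1	3
Donatia fascicularis	df51291	8	9	13	2	3	4
Donatia fascicularis	df61486	3	4	6	0	0	0
Donatia fascicularis	df79494	12	13	20	1	2	3
Donatia fascicularis	df80221	6	6	17	0	0	5
Donatia fascicularis	df80820	3	3	9	0	0	1
Donatia fascicularis	df91667	7	10	15	0	1	5
Mulguraea tridens	mt10760	4	4	5	2	2	3
Mulguraea tridens	mt11151a	8	13	20	1	5	10
Mulguraea tridens	mt11151b	3	NA	NA	1	NA	NA
Mulguraea tridens	mt14700	3	4	9	0	0	2
Mulguraea tridens	mt16240	6	6	10	1	1	5
Mulguraea tridens	mt16881	2	2	6	1	1	2
Mulguraea tridens	mt17340	4	4	6	2	2	2
Mulguraea tridens	mt17642	4	4	9	0	0	2
Mulguraea tridens	mt21753	3	5	7	0	0	1
Mulguraea tridens	mt23026	2	2	7	0	0	3
Mulguraea tridens	mt24277	4	4	5	0	0	0
Mulguraea tridens	mt25107	6	6	8	1	1	1
Mulguraea tridens	mt25266	6	7	15	2	2	9
Mulguraea tridens	mt27365	7	7	13	2	2	4
Mulguraea tridens	mt28267	1	1	13	0	0	7
Mulguraea tridens	mt30890	2	2	6	0	0	1
Mulguraea tridens	mt34724	1	1	5	0	0	1
Mulguraea tridens	mt57863	3	3	7	1	1	5
Oreobolus obtusangulus	oo12746	4	5	9	1	1	1
Oreobolus obtusangulus	oo14265	3	3	6	0	0	0
Oreobolus obtusangulus	oo16914	3	3	12	0	0	1
Oreobolus obtusangulus	oo17752	2	3	8	0	0	0
Oreobolus obtusangulus	oo20129	4	4	9	0	0	0
Oreobolus obtusangulus	oo20553	3	3	10	0	0	1
Oreobolus obtusangulus	oo25879	4	4	7	0	0	0
Oreobolus obtusangulus	oo34170	4	4	8	0	0	0
Oreobolus obtusangulus	oo40886	7	8	13	0	0	0
Oreobolus obtusangulus	oo41307	8	8	23	0	0	1
Oreobolus obtusangulus	oo48962	11	10	18	0	0	0
Oreobolus obtusangulus	oo56658	5	5	12	0	1	1
Oreobolus obtusangulus	oo59128	3	4	9	0	0	0
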