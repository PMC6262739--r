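# Per-locus fragment-size-class counts from a published amplicon-sequencing
# SSR survey of three South American angiosperm species. A class is
# homoplasious when it contains alleles of identical length but different
# sequence.
species	locus	n_size_classes	n_homoplasious
Donatia fascicularis	df14769	4	2
Donatia fascicularis	df123709	2	2
Donatia fascicularis	df124143	2	1
Donatia fascicularis	df126453	9	2
Donatia fascicularis	df137861	4	2
Donatia fascicularis	df138027	4	3
Donatia fascicularis	df142807	2	2
Donatia fascicularis	df22716	4	2
Donatia fascicularis	df51291	9	2
Donatia fascicularis	df61486	4	1
Donatia fascicularis	df79494	13	5
Donatia fascicularis	df80221	6	4
Donatia fascicularis	df80820	3	3
Donatia fascicularis	df91667	10	3
Mulguraea tridens	mt10760	3	2
Mulguraea tridens	mt11151	13	4
Mulguraea tridens	mt14700	4	3
Mulguraea tridens	mt16240	6	3
Mulguraea tridens	mt16881	2	1
Mulguraea tridens	mt17340	4	1
Mulguraea tridens	mt17642	4	2
Mulguraea tridens	mt21753	5	1
Mulguraea tridens	mt23026	2	1
Mulguraea tridens	mt24277	4	1
Mulguraea tridens	mt25107	6	2
Mulguraea tridens	mt25266	7	5
Mulguraea tridens	mt27365	7	3
Mulguraea tridens	mt28267	1	1
Mulguraea tridens	mt30890	2	1
Mulguraea tridens	mt34724	1	1
Mulguraea tridens	mt57863	3	2
Oreobolus obtusangulus	oo12746	5	2
Oreobolus obtusangulus	oo14265	3	3
Oreobolus obtusangulus	oo16914	3	2
Oreobolus obtusangulus	oo17752	3	2
Oreobolus obtusangulus	oo20129	4	2
Oreobolus obtusangulus	oo20553	3	2
Oreobolus obtusangulus	oo25879	4	2
Oreobolus obtusangulus	oo34170	4	3
Oreobolus obtusangulus	oo40886	8	4
Oreobolus obtusangulus	oo41307	8	7
Oreobolus obtusangulus	oo48962	10	5
Oreobolus obtusangulus	oo56658	5	3
Oreobolus obtusangulus	oo59128	3	3
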