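chr1	9732	9817	cell5	3
chr1	9950	10050	cell1	6000
chr1	9950	10050	cell2	5000
chr1	9950	10050	cell3	600
chr1	9980	10080	cell4	1011
chr1	10073	10183	cell5	1
chr1	10216	10390	cell5	2
chr1	10325	10441	cell5	1
chr1	10349	10514	cell8	1
chr1	10426	10552	cell8	1
chr1	19900	20000	cell6	2
chr1	19901	20001	cell8	3
chr1	19934	20128	cell8	1
chr1	20100	20200	cell1	6000
chr1	20113	20286	cell7	2
chr1	20125	20318	cell5	1
chr1	20414	20518	cell5	3
chr1	29712	29857	cell5	3
chr1	29737	29830	cell6	3
chr1	29890	29981	cell7	3
chr1	30091	30266	cell6	3
chr1	30285	30402	cell6	3
chr1	40000	40100	cell2	5000
chr1	40000	40100	cell3	11400
chr1	42000	42100	cell4	8990
chr1	45348	45433	cell6	3
chr1	45577	45712	cell7	1
chr1	45614	45727	cell5	1
chr1	45766	45907	cell6	1
chr1	45846	46012	cell7	1
chr2	4781	4923	cell7	1
chr2	4790	4982	cell6	3
chr2	4799	4921	cell7	1
chr2	4848	5047	cell7	1
chr2	5173	5278	cell8	2
chr2	5283	5446	cell7	2
chr2	50012	50201	cell6	1
chr2	50049	50143	cell6	3
chr2	50176	50373	cell5	3
chr2	50263	50384	cell7	1
chr2	60034	60147	cell6	3
chr2	60075	60195	cell6	1
chr2	60143	60333	cell8	2
chr2	60402	60562	cell6	2
chr2	60422	60561	cell5	1
chr2	60441	60552	cell5	1
chr2	60587	60731	cell8	3
chr2	60833	61025	cell6	3
chr2	60922	61007	cell6	3
chr2	60947	61106	cell8	2
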