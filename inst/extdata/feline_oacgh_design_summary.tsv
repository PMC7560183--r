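chrom	size	n_probes	mean_spacing	median_spacing	max_spacing	probes_per_mb
A1	242100913	10648	22664	17125	2635625	44
A2	171471747	7944	21469	15552	2272323	46
A3	143202405	6653	21434	16188	2630398	46
B1	208212889	9420	22001	16824	2362299	45
B2	155302638	7160	21603	16296	2303124	46
B3	149751809	7026	21173	15704	2516731	47
B4	144528695	6559	21942	16343	2103152	45
C1	222790142	10724	20646	15770	2108648	48
C2	161193150	7462	21511	16288	3159135	46
D1	117648028	5174	22610	16463	2184516	44
D2	90186660	3863	23132	16397	2155220	43
D3	96884206	4275	22564	16227	2223652	44
D4	96521652	4249	22622	16361	2213074	44
E1	63494689	2712	22955	15407	2301848	43
E2	64340295	2352	27026	18082	2536363	37
E3	44648284	1561	28241	17413	3394005	35
F1	71664243	3082	22498	16523	650963	43
F2	85752456	4137	20102	15601	333037	48
X	130557009	5455	23800	15598	2487257	42
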