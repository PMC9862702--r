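# Percentile table of the human pre-miRNA Jukes-Cantor distance distribution.
# Source model: Gaussian kernel density estimate (bandwidth 0.00973513) of the
# 1,836,486 pairwise distances among the 1917 human stem-loop sequences of
# miRBase v22.1 (www.mirbase.org, accessed 2022-12-20). The q = 100 row is the
# maximum observed distance (the KDE support is unbounded).
# Units: substitutions/site.
q	value
5	0.7321
10	0.7781
15	0.8093
20	0.8358
25	0.8583
30	0.8792
35	0.8993
40	0.9190
45	0.9388
50	0.9589
55	0.9799
60	1.0022
65	1.0262
70	1.0528
75	1.0833
80	1.1196
85	1.1656
90	1.2311
95	1.3470
100	27.0327
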