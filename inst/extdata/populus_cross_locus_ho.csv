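chromosome,locus,ho
1,LG_I_918,0.921
1,LG_I_7828,0.852
1,U16,0.875
1,U21902,0.673
2,LG_II_2319,0.770
2,Pop_02_5006,0.626
2,Pop_02_7518,0.759
3,LG_III_6624,0.767
3,Pop_03_4203,0.949
4,LG_IV_5071,0.905
4,Pop_04_3397,0.793
5,GCPM_3536-2,0.853
6,LG_VI_1534,0.876
6,Pop_06_1171,0.832
6,LG_VI_4649,0.891
7,GCPM_1054-1,0.796
7,Pop_07_2598,0.647
8,PMGC_2607,0.807
9,Pop_09_501,0.836
9,Pop_09_1080,0.824
10,PMGC_2163,0.983
10,Pop_10_2614,0.805
10,Pop_10_3412,0.819
11,Pop_11_580,0.842
11,Pop_11_827,0.908
11,GCPM_790-1,0.874
11,Pop_11_3271,0.940
12,Pop_12_1990,0.871
12,Pop_12_2242,0.839
13,Pop_13_94,0.624
13,Pop_13_293,0.968
14,Pop_14_422,0.839
14,LG_XIV_584,0.796
14,GCPM_1175-1,0.917
15,Pop_15_764,0.859
15,Pop_15_1904,0.890
15,Pop_15_2638,0.597
16,LG_XVI_2403,0.822
16,GCPM_67,0.991
16,Pop_16_1501,0.922
17,Pop_17_882,0.874
18,Pop_18_1647,0.989
18,Pop_18_1887,0.830
18,GCPM_1920-1,0.750
18,GCPM_162-1,0.963
19,Pop_19_1801,0.960
19,LG_XIX_4912,0.908
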