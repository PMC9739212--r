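id,ic50_uM,pic50,role
1,0.00825,8.08355,training
2,0.01726,7.76296,test
3,0.03126,7.50501,training
4,0.03626,7.44057,training
5,0.03637,7.43926,training
6,0.03658,7.43676,training
7,0.03768,7.42389,training
8,0.03825,7.41737,test
9,0.03834,7.41635,training
10,0.04678,7.32994,training
11,0.04736,7.32459,test
12,0.05349,7.27173,training
13,0.06000,7.22185,training
14,0.08035,7.09501,test
15,0.14856,6.82810,training
16,0.15000,6.82391,training
17,0.15000,6.82391,test
18,0.18000,6.74473,training
19,0.39000,6.40894,training
20,0.53000,6.27572,training
21,0.54000,6.26761,training
22,0.54000,6.26761,training
23,0.73232,6.13530,test
24,0.78000,6.10791,test
25,0.92000,6.03621,training
26,0.93000,6.03152,training
27,0.97000,6.01323,training
28,1.13000,5.94692,training
29,1.56000,5.80688,test
30,1.82000,5.73993,training
31,2.31000,5.63639,training
32,2.81000,5.55129,training
33,3.92000,5.40671,test
34,4.44000,5.35262,training
35,4.55000,5.34199,training
36,4.58000,5.33914,training
37,5.12000,5.29073,training
38,13.0900,4.88306,training
39,18.8000,4.72584,test
40,25.6400,4.59108,training
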