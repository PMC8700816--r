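"run","EO_CU","EO_CA","EO_CO","d32_um","pdi","ic50_mgml","bsubtilis_cfu","ecoli_cfu"
1,0.333333333333333,0.333333333333333,0.333333333333333,1.37,0.61,8.99,236600,4850000
2,0,0.5,0.5,1.55,0.63,9.126,173200,3050000
3,0.166666833333167,0.666666333333667,0.166666833333167,0.505,0.15,7,110500,4e+05
4,0.5,0,0.5,2.599,0.56,11.578,1033300,30120000
5,0.5,0,0.5,2.597,0.58,11.578,966600,40190000
6,0,0,1,4.67,0.97,15.789,2433300,60240000
7,0,0.5,0.5,1.55,0.51,9.15,57700,2745000
8,0.333333333333333,0.333333333333333,0.333333333333333,1.1,0.57,8.5,115400,8800000
9,1,0,0,2.1,0.55,10.59,606000,29300000
10,0.166666833333167,0.166666833333167,0.666666333333667,3.31,0.84,13.56,666600,24350000
11,0.666667,0.333333,0,1.8,0.444,9.986,166600,15700000
12,0.333333333333333,0.333333333333333,0.333333333333333,1.38,0.441,8.9,208200,12766000
13,0,1,0,1.67,0.6,9.865,173200,12933000
14,0.666667,0,0.333333,2,0.79,10.056,264500,23066000
15,0.333333,0.666667,0,0.523,0.23,7.3,33300,510000
16,0.5,0.5,0,1.3,0.53,8.76,208100,13666000
17,0.333333333333333,0.333333333333333,0.333333333333333,1.36,0.52,8.99,115400,9166000
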