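sex,age_group,n,baseline_mean,baseline_se,baseline_sd,scenario_a_mean,scenario_a_se,scenario_a_sd,scenario_b_mean,scenario_b_sd,scenario_c_mean,scenario_c_sd
all,all,20176,2758,21,2997,2299,12,1733,2000,2174,1500,1630
male,19-30,882,2983,64,1886,2485,40,1200,2163,1367,1623,1026
male,31-50,2077,3036,42,1910,2529,17,757,2201,1384,1652,1039
male,51-70,2246,3103,44,2081,2585,21,991,2249,1508,1688,1132
male,71+,1246,3196,45,1596,2662,13,455,2317,1157,1739,868
female,19-30,897,2236,48,1438,1866,24,719,1621,1042,1216,782
female,31-50,2288,2333,30,1445,1948,50,2373,1692,1047,1269,786
female,51-70,2420,2467,28,1373,2059,12,585,1788,995,1342,747
female,71+,1556,2525,39,1519,2108,29,1144,1831,1101,1374,826
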