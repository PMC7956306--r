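age,q_male,q_female,e_male,e_female,qd_male,qd_female,ed_male,ed_female
20,0.009005,0.010674,85.4,92.5,0.009095,0.011724,54.3,48.6
25,0.000317,0.000285,81.4,88.7,0.000486,0.001895,49.9,44.5
30,0.000221,0.000162,76.5,83.8,0.000539,0.002627,45.0,39.9
35,0.000453,0.000202,71.6,78.9,0.001050,0.003963,40.2,35.5
40,0.001134,0.000280,66.8,74.0,0.002256,0.005997,35.4,31.3
45,0.001261,0.000275,62.2,69.1,0.003365,0.008909,30.9,27.3
50,0.001265,0.000325,57.6,64.2,0.005198,0.013246,26.4,23.5
55,0.001134,0.000340,52.9,59.3,0.008439,0.019416,22.2,20.2
60,0.001270,0.000395,48.2,54.4,0.014677,0.028025,18.2,17.2
65,0.001650,0.000518,43.5,49.5,0.025737,0.039513,14.6,14.6
70,0.002431,0.000740,38.9,44.6,0.054135,0.060454,11.6,12.5
75,0.003742,0.001048,34.4,39.8,0.085696,0.077951,9.1,10.8
80,0.005241,0.001447,30.1,35.0,0.124647,0.096128,7.3,9.4
85,0.007708,0.002037,25.9,30.2,0.165352,0.113471,6.1,8.4
90,0.010964,0.003079,21.9,25.6,0.201444,0.129209,5.3,7.6
95,0.017031,0.005315,18.2,21.0,0.231195,0.143675,4.7,7.0
100,0.025290,0.009638,14.7,16.6,0.255807,0.158651,4.4,6.3
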