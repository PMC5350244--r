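pair,max_slope,min_slope,plateau_begin,plateau_end
1,0.657721015,0.936337338,0.417005168,0.986805014
2,0.010577057,0.064029034,0.097578139,0.317799703
3,0.000196868,0.303675632,0.066103149,0.019539292
4,2.66550e-19,4.10299e-06,2.01957e-15,0.000686408
5,7.86896e-19,9.69148e-05,2.93382e-15,0.001116038
6,2.92339e-26,8.04271e-09,8.07804e-27,3.30665e-15
7,0.729215365,0.637028887,0.841677533,0.687908256
8,0.734146578,0.411370955,0.302637642,0.819808126
9,6.67436e-05,0.263113108,0.006803160,0.000531943
10,0.665538015,0.024729645,0.976871651,0.131110278
11,0.018054682,0.002703960,0.285120361,0.004076710
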