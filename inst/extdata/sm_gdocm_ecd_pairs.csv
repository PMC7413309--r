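cornea,sm_ecd,gdocm_ecd,percent_difference
1,2137,2151,0.7
2,2247,2272,1.1
3,2976,2865,-3.7
4,3021,3171,5.0
5,2747,2971,8.2
6,2717,3053,12.4
7,2732,2977,9.0
8,2809,2835,0.9
9,2849,2844,-0.2
10,2809,2901,3.3
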