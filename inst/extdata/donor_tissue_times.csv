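cornea,age,death_to_cooling_h,death_to_preservation_h,preservation_to_sm_h,sm_to_gdocm_h
1,69,1.3,8.4,9.9,144.5
2,69,1.3,8.3,9.8,167.6
3,69,2.9,18.6,20.3,168.6
4,69,2.9,18.5,20.5,166.7
5,57,1.4,10.3,12.9,173.5
6,57,1.4,10.2,13.0,172.7
7,62,6.5,13.7,9.6,124.3
8,62,6.5,13.8,9.4,124.5
9,66,2.5,4.6,56.7,51.1
10,66,2.5,4.5,56.7,53.2
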