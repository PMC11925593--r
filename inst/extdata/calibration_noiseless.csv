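true_temp_C,vout_mV
30,284.70000000000005
35,335.40000000000003
40,386.1
45,436.8
50,487.5
55,538.2
60,588.9000000000001
65,639.6
70,690.3000000000001
75,741
80,791.7
85,842.4000000000001
90,893.1
95,943.8000000000001
100,994.5
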