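subject,lstm,stack_lstm,bilstm
1,50.71,51.9,50.48
2,62.38,59.05,61.9
3,53.81,53.33,53.57
4,67.38,68.1,70.95
5,48.1,48.81,47.38
6,59.52,63.81,61.9
7,65.24,66.43,66.19
8,63.1,68.57,68.33
9,54.05,55.24,55
10,46.9,49.05,51.43
11,60.95,61.9,60.48
12,52.14,58.33,58.57
13,62.38,60.71,59.52
14,62.62,59.05,63.1
15,58.57,67.86,59.52
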