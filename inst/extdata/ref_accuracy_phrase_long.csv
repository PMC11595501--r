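subject,lstm,stack_lstm,bilstm
1,69.64,67.14,68.21
2,64.64,68.93,71.79
3,85.36,77.86,86.79
4,75.71,64.29,73.93
5,68.57,70,70.71
6,75.36,79.64,77.5
7,82.14,85.36,83.21
8,78.57,75,77.14
9,69.64,73.93,64.29
10,72.86,68.21,74.64
11,77.14,64.64,75.71
12,86.43,78.21,87.5
13,68.21,63.57,66.43
14,66.07,66.07,68.21
15,81.07,70.71,81.79
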