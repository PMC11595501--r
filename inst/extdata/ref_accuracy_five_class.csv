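subject,lstm,stack_lstm,bilstm
1,41.57,44.43,41.29
2,41.14,48,42.71
3,43.29,48.29,45.57
4,47.43,49.43,48.43
5,37.14,41,39.57
6,41.43,49.43,42.71
7,50.14,49.71,49.57
8,43.43,43.57,43.29
9,40.43,42,41.71
10,34.14,41.14,40
11,45.29,48.57,43.14
12,34.71,41.71,39.86
13,33.57,36.57,34.29
14,43.14,47,43.43
15,33.71,39.71,38
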