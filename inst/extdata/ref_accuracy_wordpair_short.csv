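subject,hello_yes.lstm,hello_yes.stack_lstm,hello_yes.bilstm,stop_yes.lstm,stop_yes.stack_lstm,stop_yes.bilstm,hello_stop.lstm,hello_stop.stack_lstm,hello_stop.bilstm
1,72.5,70,78.57,72.5,59.29,71.43,87.14,75.36,86.79
2,71.79,64.64,74.29,68.21,68.57,70,79.64,68.57,73.57
3,65,63.57,66.43,76.79,83.57,82.14,74.64,71.79,76.79
4,83.93,80.71,82.5,73.93,68.21,67.14,75.36,68.21,75.36
5,73.93,65,71.07,71.79,66.07,72.86,76.43,55,78.21
6,72.86,73.93,79.64,68.93,71.79,71.79,77.86,67.14,75.71
7,66.07,68.57,64.64,77.5,71.07,73.93,74.29,68.21,75.36
8,79.29,72.5,78.21,82.5,79.29,82.5,87.86,80.71,87.14
9,68.21,63.57,69.29,71.43,66.43,71.07,71.43,70.36,70.71
10,75.71,65.36,75.71,61.79,63.93,66.43,68.93,67.5,71.79
11,76.06,66.79,77.86,66.79,68.93,72.5,77.86,57.14,76.06
12,67.14,63.57,68.57,62.86,62.5,60.71,68.57,66.79,68.21
13,65.36,61.79,68.93,70.36,65.36,71.07,80.36,59.64,85.36
14,80,68.21,80,68.93,69.29,69.64,78.93,70.36,83.93
15,71.07,64.29,73.93,78.57,72.5,79.29,80.71,68.21,81.43
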