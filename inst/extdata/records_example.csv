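Date,Time,Standing,Drinking,LyingDown,Feeding
2023-10-08,09:15:03,8,1,10,3
2023-10-08,09:15:04,8,2,9,3
2023-10-08,09:15:05,9,2,9,2
2023-10-08,09:15:06,9,1,9,3
2023-10-08,09:15:07,8,0,11,3
2023-10-08,09:15:08,8,0,12,2
2023-10-08,09:15:09,9,0,12,1
2023-10-08,09:15:10,9,0,12,1
2023-10-08,09:15:11,8,0,12,2
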