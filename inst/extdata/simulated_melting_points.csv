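ratio,POP/POST,POP/STOST,POST/STOST
0/100,34.4,38.9,38.9
10/90,28.5,43.5,30.0
20/80,26.4,33.8,33.6
30/70,20.5,30.4,30.4
40/60,22.4,28.9,34.7
50/50,18.8,28.8,33.6
60/40,21.1,23.6,31.4
70/30,23.2,19.5,24.9
80/20,24.4,15.6,20.4
90/10,28.3,16.3,26.9
100/0,33.5,33.5,34.4
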