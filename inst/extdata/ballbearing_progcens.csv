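# Progressively type-II censored ball-bearing fatigue failure times
# (classical deep-groove ball bearing endurance data, scaled; 18 of 23
# units observed, removals applied during the test).
# Shape parameter treated as known for this dataset.
# n=23 m=18 beta=0.332
time,removed
0.1788,0
0.3300,0
0.4152,0
0.4560,0
0.4848,0
0.5186,0
0.5196,0
0.5412,0
0.5556,0
0.6780,0
0.6864,0
0.8412,1
0.9312,0
0.9864,1
1.0584,0
1.2792,1
1.2804,0
1.7340,2
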