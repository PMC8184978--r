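id,episode_type,mean_euthymic,mean_episode,interpretation
1,D,96.1,139.1,more
2,M,153.8,124.6,less
3,D,100.4,109.1,more
4,M,51.2,61.7,more
8,M,91.9,92.9,more
9,D,171.3,211.0,more
11,D,186.2,192.0,more
15,D,110.7,166.2,more
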