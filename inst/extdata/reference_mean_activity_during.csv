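id,episode_type,mean_euthymic,mean_episode,interpretation
1,D,108.403,87.236,less
2,M,145.258,144.386,less
3,D,94.089,96.359,more
4,M,49.156,54.576,more
8,M,94.559,112.914,more
9,D,196.669,196.399,less
11,D,186.464,168.594,less
15,D,121.871,137.651,more
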