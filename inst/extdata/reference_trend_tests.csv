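id,episode_type,indicator,z,tau,n,p,direction
1,D,variance,3.319,0.444,28,0.001,increase
1,D,kurtosis,1.857,0.249,28,0.066,increase
1,D,acf720,1.663,0.233,28,0.096,increase
2,M,variance,0.988,0.132,28,0.336,increase
2,M,kurtosis,0.553,0.074,28,0.597,increase
2,M,acf720,-2.736,-0.380,28,0.006,decrease
3,D,variance,0.909,0.122,28,0.377,increase
3,D,kurtosis,-1.976,-0.265,28,0.05,increase
3,D,acf720,-5.719,-0.783,28,0.001,decrease
4,M,variance,2.015,0.270,28,0.045,increase
4,M,kurtosis,-3.714,-0.497,28,0.001,increase
4,M,acf720,2.894,0.419,28,0.004,increase
8,M,variance,-3.161,-0.423,28,0.001,increase
8,M,kurtosis,2.134,0.286,28,0.034,increase
8,M,acf720,-2.341,-0.328,28,0.019,decrease
9,D,variance,0.198,0.026,28,0.860,increase
9,D,kurtosis,1.936,0.259,28,0.055,increase
9,D,acf720,-3.935,-0.553,28,0.001,decrease
11,D,variance,0.121,0.019,21,0.929,increase
11,D,kurtosis,0.846,0.133,21,0.420,increase
11,D,acf720,-0.799,-0.132,21,0.424,decrease
15,D,variance,3.161,0.423,28,0.001,increase
15,D,kurtosis,-3.082,-0.413,28,0.002,increase
15,D,acf720,-1.013,-0.139,28,0.311,decrease
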