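trainee,plan,raw_score,percentage_score
1,initial,46.69,28.47
2,initial,30.64,18.68
3,initial,37.53,22.88
4,initial,16.83,10.26
5,initial,45.42,27.70
1,final,89.54,54.60
2,final,85.18,51.94
3,final,88.96,54.24
4,final,83.56,50.95
5,final,77.74,47.40
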