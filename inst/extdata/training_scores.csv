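trainee,case,raw_score,score_difference
1,easy1,129.02,11.9
2,easy1,133.84,16.74
3,easy1,138.49,21.39
4,easy1,126.8,9.7
5,easy1,132.71,15.61
1,easy2,120.51,1.77
2,easy2,144.27,25.53
3,easy2,128.36,9.62
4,easy2,136.75,18.01
5,easy2,133.79,15.05
1,intermediate1,54.75,3.53
2,intermediate1,56.49,5.27
3,intermediate1,70.42,19.2
4,intermediate1,55.08,3.86
5,intermediate1,48.27,-2.95
1,hard1,60.66,33.48
2,hard1,44.78,17.6
3,hard1,48.32,21.14
4,hard1,34.7,7.52
5,hard1,50.4,23.22
1,hard2,83.91,14.68
2,hard2,72.32,3.09
3,hard2,73.17,3.94
4,hard2,73.72,4.49
5,hard2,80.91,11.68
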