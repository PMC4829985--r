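sex,age_months,L,M,S
0,48,-1.8,15.3,0.078
0,54,-1.824,15.3516,0.0807
0,60,-1.848,15.4104,0.0834
0,66,-1.872,15.4764,0.0861
0,72,-1.896,15.5496,0.0888
0,78,-1.92,15.63,0.0915
0,84,-1.944,15.7176,0.0942
0,90,-1.968,15.8124,0.0969
0,96,-1.992,15.9144,0.0996
0,102,-2.016,16.0236,0.1023
0,108,-2.04,16.14,0.105
0,114,-2.064,16.2636,0.1077
0,120,-2.088,16.3944,0.1104
1,48,-1.8,15.6,0.078
1,54,-1.824,15.6396,0.0807
1,60,-1.848,15.6864,0.0834
1,66,-1.872,15.7404,0.0861
1,72,-1.896,15.8016,0.0888
1,78,-1.92,15.87,0.0915
1,84,-1.944,15.9456,0.0942
1,90,-1.968,16.0284,0.0969
1,96,-1.992,16.1184,0.0996
1,102,-2.016,16.2156,0.1023
1,108,-2.04,16.32,0.105
1,114,-2.064,16.4316,0.1077
1,120,-2.088,16.5504,0.1104
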