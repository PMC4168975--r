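scale,A,R,N,D,C,Q,E,G,H,I,L,K,M,F,P,S,T,W,Y,V
abraham_leo,0.44,-2.42,-1.32,-0.31,0.58,-0.71,-0.34,0.00,-0.01,2.46,2.46,-2.45,1.10,2.54,1.29,-0.84,-0.41,2.56,1.63,1.73
black_mould,0.616,0.000,0.236,0.028,0.680,0.251,0.043,0.501,0.165,0.943,0.943,0.283,0.738,1.000,0.711,0.359,0.450,0.878,0.880,0.825
engelman_ges,1.60,-12.30,-4.80,-9.20,2.00,-4.10,-8.20,1.00,-3.00,3.10,2.80,-8.80,3.40,3.70,-0.20,0.60,1.20,1.90,-0.70,2.60
bull_breese,0.610,0.690,0.890,0.610,0.360,0.970,0.510,0.810,0.690,-1.450,-1.650,0.460,-0.660,-1.520,-0.170,0.420,0.290,-1.200,-1.430,-0.750
cowan_whittaker,0.35,-1.50,-0.99,-2.15,0.76,-0.93,-1.95,0.00,-0.65,1.83,1.80,-1.54,1.10,1.69,0.84,-0.63,-0.27,1.35,0.39,1.32
eisenberg,0.62,-2.53,-0.78,-0.90,0.29,-0.85,-0.74,0.48,-0.40,1.38,1.06,-1.50,0.64,1.19,0.12,-0.18,-0.05,0.81,0.26,1.08
fauchere_pliska,0.31,-1.01,-0.60,-0.77,1.54,-0.22,-0.64,0.00,0.13,1.80,1.70,-0.99,1.23,1.79,0.72,-0.04,0.26,2.25,0.96,1.22
guy,0.10,1.91,0.48,0.78,-1.42,0.95,0.83,0.33,-0.50,-1.13,-1.18,1.40,-1.59,-2.12,0.73,0.52,0.07,-0.51,-0.21,-1.27
hopp_woods,-0.50,3.00,0.20,3.00,-1.00,0.20,3.00,0.00,-0.50,-1.80,-1.80,3.00,-1.30,-2.50,0.00,0.30,-0.40,-3.40,-2.30,-1.50
janin,0.30,-1.40,-0.50,-0.60,0.90,-0.70,-0.70,0.30,-0.10,0.70,0.50,-1.80,0.40,0.50,-0.30,-0.10,-0.20,0.30,-0.40,0.60
kyte_doolittle,1.80,-4.50,-3.50,-3.50,2.50,-3.50,-3.50,-0.40,-3.20,4.50,3.80,-3.90,1.90,2.80,-1.60,-0.80,-0.70,-0.90,-1.30,4.20
manavalan,12.97,11.72,11.42,10.85,14.63,11.76,11.89,12.43,12.16,15.67,14.90,11.36,14.39,14.00,11.37,11.23,11.69,13.93,13.42,15.71
miyazawa_jernigan,5.33,4.18,3.71,3.59,7.93,3.87,3.65,4.48,5.10,8.83,8.47,2.95,8.95,9.03,3.87,4.09,4.49,7.66,5.89,7.63
parker,2.10,4.20,7.00,10.00,1.40,6.00,7.80,5.70,2.10,-8.00,-9.20,5.70,-4.20,-9.20,2.10,6.50,5.20,-10.00,-1.90,-3.70
rao_argos,1.36,0.15,0.33,0.11,1.27,0.33,0.25,1.09,0.68,1.44,1.47,0.09,1.42,1.57,0.54,0.97,1.08,1.00,0.83,1.37
roseman,0.39,-3.95,-1.91,-3.81,0.25,-1.30,-2.91,0.00,-0.64,1.82,1.82,-2.77,0.96,2.27,0.99,-1.24,-1.00,2.13,1.47,1.30
tanford,0.62,-2.53,-0.78,-0.90,0.29,-0.85,-0.74,0.48,-0.40,1.38,1.53,-1.50,0.64,1.19,0.12,-0.18,-0.05,0.81,0.26,1.80
welling,-0.15,0.58,-0.77,0.65,-0.12,-0.11,-0.71,-0.18,0.12,-2.45,-2.87,0.22,-1.41,-2.26,-0.44,0.84,0.52,-1.65,0.21,-1.27
wilson,-0.30,-1.10,-0.20,-1.40,6.30,-0.20,0.00,1.20,-1.30,4.30,6.60,-3.60,2.50,7.50,2.20,-0.60,-2.20,7.90,7.10,5.90
wolfenden,1.94,-19.92,-9.68,-10.95,-1.24,-9.38,-10.20,2.39,-10.27,2.15,2.28,-9.52,-1.48,-0.76,0.00,-5.06,-4.88,-5.88,-6.11,1.99
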