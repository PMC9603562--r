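concentration_M,gamma_N_per_m,theta_deg
1e-05,0.0708889437411803,121.149968528735
3e-05,0.0681627479452234,114.166984860793
1e-04,0.05055556727189,92.6781975049749
3e-04,0.0341838917057187,64.0011094342725
0.001,0.0302955358048496,59.9242092561108
0.003,0.0295441134676889,60.9210018583682
0.01,0.0310627762615883,55.6714229784388
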