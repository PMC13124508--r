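{"coupling_graph":[[0,0.8,0.8,0],[0,0,0,0.8],[0,0,0,0],[0,0,0,0]],"frequencies":[0.0416666666666667,0.0833333333333333,0.125,0.166666666666667],"amplitudes":[1,1,1,1],"coupling_lag":1,"seed":12,"switch_graph":false}
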