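rate_x,rate_y,rho_min,rho_max
3,3,-0.940990485626,1.000000000000
2,4,-0.967586227805,0.907987483629
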