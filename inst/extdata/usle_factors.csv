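class,c_factor,p_factor
forest,0.025,1
grassland,0.034,1
water,0,1
urban,0.99,1
unused,0.85,1
paddy,0.412,0.2
dry,0.412,0.6
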