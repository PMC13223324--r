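class,kc,root_depth_mm
forest,1.008,7000
grassland,0.85,2600
water,0.975,10
urban,0.2,1
unused,0.75,5000
paddy,1.125,2000
dry,0.954,2000
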