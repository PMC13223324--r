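class,area_1990_km2,area_2020_km2
forest,23659,23550
grassland,11015,8065
water,12854,14969
urban,30542,40234
unused,741,165
paddy,51555,49807
dry,131038,124614
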