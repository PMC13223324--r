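service,unit,class,y1990,y2020,change_printed,pct_printed
carbon,1e8 t,forest,12.0598,11.9858,-0.0740,-1
carbon,1e8 t,grassland,0.3402,0.2549,-0.0853,-25
carbon,1e8 t,water,0.2480,0.3053,0.0573,23
carbon,1e8 t,urban,0.2933,0.3933,0.0999,34
carbon,1e8 t,unused,0.0188,0.0070,-0.0117,-63
carbon,1e8 t,paddy,0.7578,0.7285,-0.0293,-4
carbon,1e8 t,dry,1.6862,1.5981,-0.0880,-5
habitat,sum Q,forest,18548.55,18867.44,318.889,2
habitat,sum Q,grassland,6091.1439,4979.6028,-1111.5411,-18
habitat,sum Q,water,2240.899,2818.272,577.373,26
food_material,1e8 Yuan,forest,28.7966,28.6198,-0.1768,-1
food_material,1e8 Yuan,grassland,11.2252,8.4116,-2.8136,-25
food_material,1e8 Yuan,water,10.992,13.531,2.539,23
food_material,1e8 Yuan,paddy,110.3017,106.0418,-4.2599,-4
food_material,1e8 Yuan,dry,244.1407,231.397,-12.7431,-5
erosion,1e4 t,forest,251.194,899.043,647.849,258
erosion,1e4 t,grassland,142.351,395.154,252.803,178
erosion,1e4 t,urban,764.8605,1872.404,1107.544,145
erosion,1e4 t,unused,36.151,28.7228,-7.4282,-21
erosion,1e4 t,paddy,112.9683,451.0758,338.1075,299
erosion,1e4 t,dry,1394.962,2013.20,618.238,44
water_yield,1e8 m3,forest,0.0380,0.0922,0.0542,142
water_yield,1e8 m3,grassland,0.0243,0.0270,0.0027,11
water_yield,1e8 m3,water,0.0020,0.0098,0.0078,390
water_yield,1e8 m3,urban,0.2116,0.3125,0.1009,48
water_yield,1e8 m3,unused,0.0009,0.0003,-0.0006,-64
water_yield,1e8 m3,paddy,0.0470,0.0896,0.0426,91
water_yield,1e8 m3,dry,0.1193,0.1539,0.0347,29
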