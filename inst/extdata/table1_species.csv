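species,common_name,n,mass_kg,mass_sd_kg,hip_height_m,hip_height_sd_m,leg_length_m,leg_length_sd_m
Coturnix chinensis,Chinese painted quail,5,0.047,0.002,0.0586,0.004,0.084,0.0032
Colinus virginianus,Northern bobwhite quail,5,0.17,0.014,0.0778,0.0104,0.1332,0.0028
Coturnix japonica,Japanese quail,4,0.301,0.077,0.1063,0.0075,0.1405,0.0087
Porphyrio porphyrio,Purple swamphen,3,0.623,0.058,0.239,0.0141,0.2877,0.0091
Eudromia elegans,Elegant-crested tinamou,3,0.756,0.013,0.172,0.0067,NA,NA
Numida meleagris,Helmeted guineafowl,3,1.257,0.114,0.2017,0.0155,0.2493,0.0083
Alectura lathami,Australian brush turkey,2,1.49,0.057,0.267,0.0156,0.3095,0.0021
Threskiornis moluccus,Australian white ibis,2,1.54,0.057,0.2825,0.0304,0.342,0.0156
Gallus gallus,Domestic chicken,3,1.71,0.521,0.2543,0.0478,0.2843,0.0438
Meleagris gallopavo,Domestic turkey,5,3.228,0.9,0.3652,0.0474,0.4068,0.0493
Dromaius novaehollandiae,Emu,6,38.58,2.69,0.9033,0.035,1.0055,0.0259
Struthio camelus,Ostrich,3,74.35,6.15,1.128,0.0141,1.181,0
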