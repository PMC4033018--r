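species,specimen_id,corticobasolateral_amygdala,centromedial_amygdala,amygdala,hippocampus,schizocortex,septal_nuclei,striatum,hemisphere
Homo sapiens,s1,1.990,0.653,2.643,5.144,3.071,1.305,14.345,
Pan troglodytes,s1,0.523,0.188,0.711,1.890,1.009,0.426,6.123,
Gorilla gorilla,s1,0.999,0.377,1.376,2.391,1.365,0.587,7.284,
Hylobates lar,s1,0.255,0.078,0.333,1.337,0.568,0.151,2.392,
Papio anubis,s1,0.370,0.107,0.477,1.699,0.655,0.280,3.591,
Macaca mulatta,s1,0.247,0.093,0.339,0.677,0.320,0.136,2.016,
Erythrocebus patas,s1,0.245,0.100,0.344,0.796,0.347,0.165,1.812,
Cercocebus albigena,s1,0.258,0.133,0.391,0.743,0.315,0.147,2.073,
Cercopithecus ascanius,s1,0.217,0.070,0.286,0.595,0.347,0.126,1.414,
Cercopithecus mitis,s1,0.247,0.105,0.352,0.683,0.309,0.123,1.367,
Cercopithecus talapoin,s1,0.156,0.051,0.207,0.353,0.130,0.067,0.954,
Lagothrix lagotricha,s1,0.283,0.094,0.377,0.793,0.340,0.133,2.474,
Colobus badius,s1,0.189,0.062,0.250,0.836,0.407,0.144,1.609,
Pygathrix nemaeus,s1,0.169,0.076,0.245,1.148,0.362,0.145,1.583,
Nasalis larvatus,s1,0.250,0.110,0.359,0.983,0.428,0.167,1.868,
Cebuella pygmaea,s1,0.029,0.009,0.038,0.067,0.041,0.015,0.087,
Callimico goeldii,s1,0.056,0.018,0.073,0.141,0.069,0.032,0.247,
Cebus sp.,s1,0.169,0.060,0.229,0.445,0.195,0.087,1.629,
Saimiri sciureus,s1,0.094,0.027,0.121,0.176,0.084,0.045,0.521,
Pithecia monacha,s1,0.137,0.046,0.183,0.417,0.145,0.070,0.959,
Alouatta sp.,s1,0.162,0.051,0.213,0.660,0.255,0.100,1.415,
Ateles geoffroyi,s1,0.322,0.112,0.434,0.683,0.366,0.162,2.475,
Callithrix jacchus,s1,0.038,0.015,0.053,0.111,0.045,0.025,0.186,
Saguinus oedipus,s1,0.055,0.016,0.071,0.131,0.054,0.030,0.227,
Aotus trivirgatus,s1,0.068,0.028,0.097,0.270,0.122,0.042,0.431,
Callicebus moloch,s1,0.090,0.037,0.127,0.294,0.117,0.043,0.460,
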