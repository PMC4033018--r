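species,specimen_id,lateral_nucleus,basal_nucleus,accessory_basal_nucleus,central_nucleus,amygdala,hippocampus,striatum,hemisphere
Homo sapiens,hs1,0.551,0.452,0.188,0.039,2.031,5.180,9.551,
Homo sapiens,hs2,–,–,–,–,–,–,12.223,
Pan troglodytes,pt1,0.138,0.224,0.070,0.065,0.685,1.772,5.159,
Pan troglodytes,pt2,0.126,0.183,0.070,0.056,0.584,1.520,4.373,
Pan troglodytes,pt3,0.115,0.176,0.066,0.037,0.571,–,–,
Pan troglodytes,pt4,0.095,0.117,0.047,0.024,0.417,–,–,
Pan troglodytes,pt5,0.165,0.263,0.064,0.049,0.749,–,–,
Pan paniscus,pp1,0.164,0.191,0.066,0.042,0.634,1.710,5.645,
Pan paniscus,pp2,0.124,0.223,0.070,0.032,0.623,1.595,4.400,
Gorilla gorilla,gg1,0.100,0.247,0.096,0.037,0.651,1.350,4.626,
Gorilla gorilla,gg2,0.167,0.266,0.112,0.053,0.867,–,–,
Gorilla gorilla,gg3,0.137,0.170,0.105,0.043,0.645,–,–,
Pongo pygmaeus,po1,0.124,0.228,0.062,0.047,0.637,1.255,–,
Pongo pygmaeus,po2,0.105,0.151,0.052,0.036,0.520,1.415,3.689,
Pongo pygmaeus,po3,0.157,0.171,0.071,0.030,0.638,–,–,
Pongo pygmaeus,po4,0.156,0.171,0.067,0.045,0.725,–,–,
Pongo pygmaeus,po5,–,–,–,–,–,1.645,4.498,
Hylobates lar,hl1,0.046,0.063,0.021,0.009,0.203,0.805,1.510,
Nomascus concolor,nc1,0.060,0.086,0.022,0.012,0.270,0.950,1.994,
Hylobates muelleri,hm1,0.069,0.079,0.030,0.017,0.256,–,–,
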