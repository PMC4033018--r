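species,specimen_id,orbital_frontal_cortex,medial_frontal_cortex,dorsal_frontal_cortex,insular_cortex,hemisphere
Homo sapiens,hs1,41.3,68.2,144.6,16.6,
Homo sapiens,hs2,41.3,83.0,179.9,18.8,
Homo sapiens,hs3,33.6,67.3,149.1,14.6,
Homo sapiens,hs4,31.2,66.9,137.7,17.7,
Homo sapiens,hs5,45.6,86.0,174.8,19.0,
Homo sapiens,hs6,44.7,81.7,166.7,18.0,
Homo sapiens,hs7,43.4,90.5,191.5,16.9,
Homo sapiens,hs8,30.0,74.6,185.4,16.5,
Homo sapiens,hs9,35.5,68.9,161.1,15.2,
Homo sapiens,hs10,41.6,67.4,151.3,20.3,
Pan paniscus,pp1,9.0,19.1,35.1,3.5,
Pan paniscus,pp2,13.4,18.2,38.7,4.1,
Pan paniscus,pp3,9.3,17.9,33.3,3.4,
Pan troglodytes,pt1,9.5,15.8,32.6,2.6,
Pan troglodytes,pt2,6.9,12.7,30.3,2.5,
Pan troglodytes,pt3,9.6,15.7,29.6,3.5,
Pan troglodytes,pt4,13.5,22.5,48.4,4.0,
Pan troglodytes,pt5,8.7,17.7,40.5,3.0,
Gorilla gorilla,gg1,11.4,19.7,43.1,3.5,
Gorilla gorilla,gg2,14.7,26.3,52.9,7.1,
Pongo pygmaeus,po1,9.0,30.1,53.7,5.9,
Pongo pygmaeus,po2,12.0,33.1,66.5,4.3,
Pongo pygmaeus,po3,10.8,28.3,65.2,5.3,
Pongo pygmaeus,po4,7.1,22.7,46.0,3.7,
Hylobates lar,hl1,2.1,3.6,7.7,0.8,
Hylobates lar,hl2,2.4,3.7,7.2,0.7,
Hylobates lar,hl3,2.4,4.2,8.3,0.6,
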