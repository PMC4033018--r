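((((Homo_sapiens:7,(Pan_troglodytes:2.5,Pan_paniscus:2.5):4.5):2,Gorilla_gorilla:9):7,Pongo_pygmaeus:16):4,((Hylobates_lar:4,Hylobates_muelleri:4):4,Nomascus_concolor:8):12);
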