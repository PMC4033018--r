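(((((Homo_sapiens:7,Pan_troglodytes:7):2,Gorilla_gorilla:9):11,Hylobates_lar:20):10,((Colobus_badius:12,(Pygathrix_nemaeus:8,Nasalis_larvatus:8):4):6,((Macaca_mulatta:12,(Papio_anubis:9,Cercocebus_albigena:9):3):2,((Erythrocebus_patas:9,(Cercopithecus_ascanius:6,Cercopithecus_mitis:6):3):3,Cercopithecus_talapoin:12):2):4):12):10,((Pithecia_monacha:20,Callicebus_moloch:20):5,((Alouatta_sp.:18,(Ateles_geoffroyi:12,Lagothrix_lagotricha:12):6):5,((Cebus_sp.:16,Saimiri_sciureus:16):4,(Aotus_trivirgatus:18,(Saguinus_oedipus:12,(Callimico_goeldii:9,(Callithrix_jacchus:6,Cebuella_pygmaea:6):3):3):6):2):3):2):15);
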