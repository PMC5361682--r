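(Opossum:0.45,((Tree_shrew:0.25,(Pika:0.3,((Mouse:0.12,Rat:0.12):0.08,(Hamster:0.15,Prairie_vole:0.15):0.06):0.07):0.02):0.02,((Hedgehog:0.3,(Shrew:0.3,Star_nosed_mole:0.25):0.04):0.04,(Ferret:0.25,(Naked_mole_rat:0.55,(Eptesicus_fuscus:0.12,(Myotis_brandtii:0.06,Myotis_lucifugus:0.06):0.05):0.1):0.1):0.02):0.02):0.02);
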