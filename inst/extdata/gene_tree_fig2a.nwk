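(Opossum,((Tree_shrew,(Pika,((Mouse,Rat),(Hamster,Prairie_vole)))),((Hedgehog,(Shrew,Star_nosed_mole)),(Ferret,(Naked_mole_rat,(Eptesicus_fuscus,(Myotis_brandtii,Myotis_lucifugus)))))));
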