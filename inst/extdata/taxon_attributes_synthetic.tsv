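# Per-taxon attributes. Longevities are AnAge-style maxima; body masses are
# representative placeholder values (synthetic, not from the study data).
species	mass_g	max_longevity_yr	focal	group
Naked_mole_rat	35	31	TRUE	rodent
Myotis_brandtii	6	41	TRUE	bat
Myotis_lucifugus	7.5	34	TRUE	bat
Eptesicus_fuscus	18	19	TRUE	bat
Mouse	20	4	FALSE	rodent
Rat	300	3.8	FALSE	rodent
Hamster	105	3.9	FALSE	rodent
Prairie_vole	45	2.8	FALSE	rodent
Pika	155	7	FALSE	lagomorph
Tree_shrew	180	11	FALSE	scandentian
Shrew	8	3.2	FALSE	eulipotyphlan
Star_nosed_mole	50	2.5	FALSE	eulipotyphlan
Hedgehog	750	11.7	FALSE	eulipotyphlan
Ferret	1000	11.1	FALSE	carnivore
Opossum	1200	6.6	FALSE	marsupial
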