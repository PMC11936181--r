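compound_id,gi_absorption,bbb_permeant,pgp_substrate,gpcr_ligand,ion_channel_modulator,kinase_inhibitor,nuclear_receptor_ligand,protease_inhibitor,enzyme_inhibitor,oral_ld50_mg_kg,hepatotoxicity,neurotoxicity,nephrotoxicity,respiratory_toxicity,cardiotoxicity
Corilagin,Low,No,Yes,-0.11,-0.71,-0.45,-0.44,-0.03,-0.15,2260,inactive,inactive,active,active,inactive
Apigetrin,Low,No,Yes,0.10,-0.01,0.14,0.31,0.02,0.43,5000,inactive,inactive,active,active,active
Protopine,High,Yes,Yes,0.18,-0.04,-0.26,-0.23,-0.03,0.04,940,inactive,active,inactive,active,inactive
5-methoxyflavone,High,Yes,Yes,-0.18,-0.18,0.04,0.03,-0.37,0.07,4000,inactive,inactive,active,active,inactive
"7,3',4'-trihydroxyisoflavone",High,Yes,Yes,-0.24,-0.60,-0.10,0.11,-0.77,0.06,2500,inactive,inactive,active,active,inactive
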