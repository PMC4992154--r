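"species_id","island_id","class_volancy","outcome","extant","single_island_endemic","body_mass"
"s1","A","reptile",1,0,1,NA
"s2","A","volant_bird",0,1,0,NA
"s2","B","volant_bird",0,1,0,NA
"s3","B","nonvolant_mammal",1,0,1,NA
"s4","C","amphibian",0,1,1,NA
"s5","C","nonvolant_bird",0,1,1,NA
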