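"island_id","area","elevation","precipitation","mean_temperature","temperature_seasonality","human_presence","canids","felids","mustelids_mongooses","pigs","primates","medium_omnivores","small_omnivores","rats","mice","large_herbivores","medium_herbivores","lagomorphs","eradicated_rats","eradicated_canids","eradicated_felids","eradicated_mustelids_mongooses","eradicated_pigs","eradicated_primates","eradicated_medium_omnivores","eradicated_small_omnivores","eradicated_mice","eradicated_large_herbivores","eradicated_medium_herbivores","eradicated_lagomorphs"
"A",0.5,5,800,24,2.1,0,0,0,0,0,0,0,0,1,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0
"B",12,80,1300,21,3.5,1,0,1,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"C",300,1200,2100,18,5,1,0,1,0,1,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
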