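year,stems_per_individual,st_flowering_stems,fl_flowers_per_stem,fruits_per_flower,sound_seeds_per_fruit,s_seeds_per_stem,sa_survival,n_individuals,n_stems
2014,28.3,18.9,11.71,0.29,0.58,7.26,NA,20,40
2015,13.5,9.65,21.55,0.34,0.76,9.24,0.85,20,40
2016,22.05,13.9,24.87,0.37,0.8,20.68,0.65,20,40
2017,18.8,12.5,20.94,0.33,0.65,13.04,0.90,20,40
2018,23.5,16.95,19.78,0.3,0.6,11.47,0.95,20,40
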