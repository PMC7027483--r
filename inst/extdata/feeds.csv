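name,dm_digestibility,crude_protein,gross_energy_density,crop_yield_t_ha,is_concentrate,cultivated
pasture,0.55,0.08,18.45,NA,0,0
napier,0.65,0.10,18.45,12.0,0,1
maize_stover,0.50,0.05,18.45,NA,0,0
maize_silage,0.68,0.08,18.45,NA,0,1
concentrate,0.80,0.18,18.45,NA,1,0
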