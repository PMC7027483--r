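ingredient,composition_fraction,yield_t_ha,national_area_ha
rice_bran,0.27,2.68,97659
lime,0.04,10.78,1693
wheat_grain,0.27,1.93,85732
maize,0.27,1.52,2092459
sunflower_cake,0.05,0.97,11840
cotton_seed_cake,0.10,0.50,25980
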