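lps,scenario,yield_level,dmi,pasture,napier,maize_stover,maize_silage,concentrate,milk_fpcm,milk_increase_pct,intensity
MRA,baseline,Ya,3565,1837,818,874,0,35,1729,NA,2.64
MRA,FeCo,Ya,4391,1837,818,402,883,450,2489,44.0,2.38
MRA,FeCo,Yw50,4391,1837,818,402,883,450,2489,44.0,2.04
MRA,FeCo,Yw80,4391,1837,818,402,883,450,2489,44.0,1.93
MRA,FoFeCo,Ya,5321,72,2583,0,1765,900,2610,51.0,2.90
MRA,FoFeCo,Yw50,5321,72,2583,0,1765,900,2610,51.0,2.45
MRA,FoFeCo,Yw80,5321,72,2583,0,1765,900,2610,51.0,2.23
MRA,FoCo,Ya,3980,955,1701,874,0,450,2507,45.0,1.76
MRH,baseline,Ya,3621,1233,1321,1031,0,36,1881,NA,2.40
MRH,FeCo,Ya,4454,1233,1321,554,896,450,2708,44.0,2.16
MRH,FeCo,Yw50,4454,1233,1321,554,896,450,2708,44.0,1.97
MRH,FeCo,Yw80,4454,1233,1321,554,896,450,2708,44.0,1.94
MRH,FoFeCo,Ya,5883,0,3113,77,1793,900,2840,51.0,2.64
MRH,FoFeCo,Yw50,5883,0,3113,77,1793,900,2840,51.0,2.24
MRH,FoFeCo,Yw80,5883,0,3113,77,1793,900,2840,51.0,2.20
MRH,FoCo,Ya,4035,337,2217,1031,0,450,2727,45.0,1.71
MRT,baseline,Ya,3573,1275,1523,740,0,35,1932,NA,2.33
MRT,FeCo,Ya,4437,1275,1523,304,885,450,2782,44.0,2.10
MRT,FeCo,Yw50,4437,1275,1523,304,885,450,2782,44.0,1.94
MRT,FeCo,Yw80,4437,1275,1523,304,885,450,2782,44.0,1.89
MRT,FoFeCo,Ya,5961,0,3292,0,1769,900,2917,51.0,2.56
MRT,FoFeCo,Yw50,5961,0,3292,0,1769,900,2917,51.0,2.19
MRT,FoFeCo,Yw80,5961,0,3292,0,1769,900,2917,51.0,2.12
MRT,FoCo,Ya,3988,390,2408,740,0,450,2801,45.0,1.67
MIA,baseline,Ya,3565,1837,818,874,0,35,1736,NA,2.62
MIA,FeCo,Ya,4391,1837,818,402,883,450,2500,44.0,2.36
MIA,FeCo,Yw50,4391,1837,818,402,883,450,2500,44.0,2.05
MIA,FeCo,Yw80,4391,1837,818,402,883,450,2500,44.0,1.93
MIA,FoFeCo,Ya,5321,72,2583,0,1765,900,2621,51.0,2.88
MIA,FoFeCo,Yw50,5321,72,2583,0,1765,900,2621,51.0,2.43
MIA,FoFeCo,Yw80,5321,72,2583,0,1765,900,2621,51.0,2.24
MIA,FoCo,Ya,3980,955,1701,874,0,450,2517,45.0,1.77
MIH,baseline,Ya,3621,1233,1321,1031,0,36,1880,NA,2.40
MIH,FeCo,Ya,4454,1233,1321,554,896,450,2708,44.0,2.16
MIH,FeCo,Yw50,4454,1233,1321,554,896,450,2708,44.0,1.98
MIH,FeCo,Yw80,4454,1233,1321,554,896,450,2708,44.0,1.95
MIH,FoFeCo,Ya,5883,0,3113,77,1793,900,2839,51.0,2.64
MIH,FoFeCo,Yw50,5883,0,3113,77,1793,900,2839,51.0,2.28
MIH,FoFeCo,Yw80,5883,0,3113,77,1793,900,2839,51.0,2.20
MIH,FoCo,Ya,4035,337,2217,1031,0,450,2726,45.0,1.73
MIT,baseline,Ya,3573,1275,1523,740,0,35,1931,NA,2.34
MIT,FeCo,Ya,4437,1275,1523,304,885,450,2781,44.0,2.11
MIT,FeCo,Yw50,4437,1275,1523,304,885,450,2781,44.0,1.97
MIT,FeCo,Yw80,4437,1275,1523,304,885,450,2781,44.0,1.92
MIT,FoFeCo,Ya,5961,0,3292,0,1769,900,2916,51.0,2.57
MIT,FoFeCo,Yw50,5961,0,3292,0,1769,900,2916,51.0,2.28
MIT,FoFeCo,Yw80,5961,0,3292,0,1769,900,2916,51.0,2.25
MIT,FoCo,Ya,3988,390,2408,740,0,450,2801,45.0,1.69
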