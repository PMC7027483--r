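lps,population_dairy_cows,productive_dairy_cows,baseline_concentrate_t
MRA,246237,147742,16965
MRH,111205,66723,2513
MRT,2443342,1466005,16965
MIA,28845,17307,16965
MIH,20376,12225,3142
MIT,142081,85249,6283
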