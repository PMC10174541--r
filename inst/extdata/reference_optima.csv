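disinfectant,concentration,time_min,contamination,germination
CaClO2,8.73,13.54,4.27,90.63
NaOCl,1.89,11.97,8.03,76.27
HgCl2,5.03,4.77,7.36,72.03
H2O2,16.35,18.44,1.33,77.73
NWCNFe,8.59,16.19,33.07,56.78
MWCNT,35.63,9.93,45.63,41.07
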