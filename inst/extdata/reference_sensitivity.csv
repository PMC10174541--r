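response,input,vsr,rank
contamination,NaOCl,3.63,2
contamination,CaClO2,2.76,4
contamination,HgCl2,2.96,3
contamination,H2O2,1.36,6
contamination,NWCNFe,1.14,7
contamination,MWCNT,1.83,5
contamination,time_min,3.73,1
germination,NaOCl,1.94,2
germination,CaClO2,1.72,3
germination,HgCl2,1.11,5
germination,H2O2,1.36,4
germination,NWCNFe,1.01,6
germination,MWCNT,0.80,7
germination,time_min,2.07,1
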