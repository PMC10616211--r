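protein,residue_number,residue_aa,protein2,residue_number2,residue_aa2,linker
DID,377,K,MFN2,79,K,DSG
DID,143,K,MFN2,192,K,BS(PEG)9
DID,228,K,MFN2,132,C,SMCC
DID,164,C,MFN2,37,K,SMCC
DID,164,C,MFN2,158,K,SMCC
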