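drug,literature_pe
ref_drug_01,8.0
ref_drug_02,5.2
ref_drug_03,3.1
ref_drug_04,1.4
ref_drug_05,0.6
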