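compound,replicate,wavelength,a_donor_pre,a_receptor_post
cand_A,1,270,0.93,0.2634
cand_A,1,290,1.06,0.2962
cand_A,2,270,1.014,0.2977
cand_A,2,290,0.823,0.2472
cand_B,1,270,0.815,0.0968
cand_B,1,290,0.828,0.0929
cand_B,2,270,0.97,0.1225
cand_B,2,290,0.85,0.0975
cand_C,1,270,1.051,0.0225
cand_C,1,290,1.031,0.0203
cand_C,2,270,1.191,0.0221
cand_C,2,290,1.143,0.0221
ref_drug_01,1,270,0.858,0.3383
ref_drug_01,1,290,0.923,0.4073
ref_drug_01,2,270,0.872,0.371
ref_drug_01,2,290,1.056,0.4345
ref_drug_02,1,270,1.019,0.2843
ref_drug_02,1,290,0.824,0.2356
ref_drug_02,2,270,1.072,0.3179
ref_drug_02,2,290,0.926,0.2816
ref_drug_03,1,270,0.981,0.1709
ref_drug_03,1,290,1.118,0.2076
ref_drug_03,2,270,0.898,0.1636
ref_drug_03,2,290,1.01,0.1927
ref_drug_04,1,270,1.092,0.0844
ref_drug_04,1,290,1.192,0.0895
ref_drug_04,2,270,0.967,0.0805
ref_drug_04,2,290,0.861,0.0688
ref_drug_05,1,270,0.816,0.0251
ref_drug_05,1,290,1.106,0.0336
ref_drug_05,2,270,1.15,0.0335
ref_drug_05,2,290,1.078,0.0328
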