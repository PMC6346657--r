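sample_id	deme	lattice_position
deme1_ind1	deme1	1
deme1_ind2	deme1	1
deme1_ind3	deme1	1
deme1_ind4	deme1	1
deme1_ind5	deme1	1
deme1_ind6	deme1	1
deme1_ind7	deme1	1
deme2_ind1	deme2	2
deme2_ind2	deme2	2
deme2_ind3	deme2	2
deme2_ind4	deme2	2
deme2_ind5	deme2	2
deme2_ind6	deme2	2
deme2_ind7	deme2	2
deme3_ind1	deme3	3
deme3_ind2	deme3	3
deme3_ind3	deme3	3
deme3_ind4	deme3	3
deme3_ind5	deme3	3
deme3_ind6	deme3	3
deme3_ind7	deme3	3
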