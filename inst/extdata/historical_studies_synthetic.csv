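study_id,publication_year,sample_size,sparing_proportion
global_pediatric_2024,2024,132,0.712
aspo_2014,2014,400,0.22
cso_2019,2019,100,0.578
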