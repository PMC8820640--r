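age_group,share_marriage,share_contraception,share_abortion,share_infecundability,asfr_per_1000,n_women
15-19,83.5,2.9,8.3,5.2,51,124878
20-24,42.2,17.3,20.4,20.1,184,122955
25-29,9.9,42.2,26.9,21.1,128,115076
30-34,3.5,52.8,25.9,17.8,51,97048
35-39,3.1,52.8,30.1,14.1,17,90433
40-44,2.9,47.5,37.8,11.7,4,76627
45-49,3.1,49.7,36.8,10.5,1,72669
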