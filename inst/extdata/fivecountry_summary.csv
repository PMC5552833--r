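country,n,n_male,mean_fu_years,py_thousand,py_male_thousand,ever_human,ever_glargine,ever_detemir,ever_other_insulin
DK,66698,38292,5.3,331.2,184.4,54216,7151,9520,33388
FI,105945,57691,5.6,589.1,316.9,68894,43741,24593,48280
NO,21541,12053,2.7,57.8,32.4,17579,1447,868,14376
SE,85319,48931,2.7,226.6,131.3,48976,15138,4367,53810
UK,47609,25589,5.7,265.3,141.6,23183,15374,7373,27491
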