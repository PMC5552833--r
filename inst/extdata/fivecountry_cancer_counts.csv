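endpoint,sex,DK,FI,NO,SE,UK
liver,male,144,308,15,89,74
liver,female,28,102,NA,23,21
pancreas,male,315,531,76,238,129
pancreas,female,233,417,64,199,109
lung,male,466,623,55,192,218
lung,female,244,174,33,112,116
melanoma,male,59,130,27,80,69
melanoma,female,53,77,9,45,35
bladder,male,106,281,43,183,117
bladder,female,34,77,NA,40,28
colorectal,male,423,484,68,312,219
colorectal,female,258,366,46,145,102
nhl,male,52,180,14,68,31
nhl,female,47,132,7,46,35
breast,female,462,729,51,250,301
endometrial,female,152,289,29,107,57
prostate,male,501,1339,100,582,290
any_cancer,male,2733,5315,542,2272,1918
any_cancer,female,1950,3618,333,1361,1348
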