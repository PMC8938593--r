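subject,pet_activity_ratio_pct
R01,10.9
R02,11.7
R03,13.7
R04,27.0
R05,10.1
R06,11.7
R07,11.9
R08,16.1
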