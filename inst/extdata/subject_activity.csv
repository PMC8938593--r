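subject,mu_bkg_hu,sigma_bkg_hu,b_cal_hu,A0_mbq,A_ct_mbq,A_ct_ci_lo_mbq,A_ct_ci_hi_mbq,A_pet_mbq,A_pet_shell_mbq,rc_ct_pct,rc_pet_pct,rc_pet_shell_pct
R01,99.1,5.6,110.0,132.4,122.6,114.6,131.9,93.5,138.4,92.6,70.6,104.6
R02,69.2,3.0,75.1,171.0,119.8,111.9,128.8,124.3,176.1,70.1,72.7,103.0
R03,84.4,3.7,91.7,155.9,141.9,132.6,152.6,86.5,143.2,91.1,55.5,91.9
R04,103.8,4.2,112.1,128.1,117.9,108.7,126.8,51.4,81.9,92.1,40.1,63.9
R05,96.5,3.3,102.9,133.7,132.5,123.8,143.9,99.9,144.8,99.1,74.7,108.3
R06,109.9,3.8,117.2,171.0,158.2,147.9,171.5,109.9,164.6,92.6,64.3,96.2
R07,105.4,4.0,113.1,131.6,119.2,110.4,128.2,103.3,145.0,90.6,78.5,110.2
R08,94.8,4.9,104.3,130.2,100.8,91.7,108.4,61.5,101.4,77.4,47.2,77.9
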