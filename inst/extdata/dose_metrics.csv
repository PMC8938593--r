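subject,modality,structure,D_med,D_max,D_mu,sigma,COV,D70
R01,CT,L,5.4,1124.3,42.0,78.9,1.9,0.8
R01,CT,L_shell,0.0,1124.3,10.9,42.9,3.9,0.4
R01,CT,B,0.0,1124.3,3.5,24.9,7.1,0.3
R01,PET,L,36.7,372.0,65.3,66.0,1.0,11.3
R01,PET,L_shell,6.0,372.0,24.3,44.7,1.8,2.2
R01,PET,B,1.6,372.0,8.9,27.3,3.1,1.1
R02,CT,L,9.6,1155.8,32.6,57.8,1.8,1.8
R02,CT,L_shell,0.0,1155.8,9.2,33.2,3.6,0.4
R02,CT,B,0.0,1155.8,3.1,19.6,6.4,0.3
R02,PET,L,53.3,309.0,68.3,63.0,0.9,16.4
R02,PET,L_shell,9.3,309.1,27.3,44.4,1.6,3.7
R02,PET,B,1.9,309.0,10.2,27.8,2.7,1.1
R03,CT,L,2.6,1585.5,32.5,84.7,2.6,0.9
R03,CT,L_shell,0.0,1585.5,10.5,48.2,4.6,0.4
R03,CT,B,0.0,1585.5,4.5,31.8,7.2,0.3
R03,PET,L,15.9,345.0,42.0,55.0,1.3,10.3
R03,PET,L_shell,8.2,345.0,21.3,37.7,1.8,5.3
R03,PET,B,3.1,345.0,10.4,25.8,2.5,2.0
R04,CT,L,14.3,754.8,41.9,68.3,1.6,4.3
R04,CT,L_shell,0.0,754.8,11.3,39.0,3.4,0.2
R04,CT,B,0.0,754.8,3.9,23.5,6.0,0.1
R04,PET,L,23.4,266.0,36.9,36.3,1.0,15.4
R04,PET,L_shell,8.5,266.0,15.8,23.8,1.5,6.1
R04,PET,B,3.7,266.0,7.4,15.0,2.0,2.0
R05,CT,L,2.9,1812.3,38.4,96.3,2.5,0.8
R05,CT,L_shell,0.1,1812.3,16.4,64.3,3.9,0.4
R05,CT,B,0.0,1812.3,3.7,31.0,8.4,0.3
R05,PET,L,21.7,389.0,58.5,66.0,1.1,9.4
R05,PET,L_shell,6.5,389.3,22.7,43.0,1.9,2.1
R05,PET,B,1.6,389.0,9.0,27.1,3.0,1.0
R06,CT,L,13.6,1375.6,49.7,91.2,1.8,3.3
R06,CT,L_shell,0.0,1375.6,13.5,50.5,3.7,0.5
R06,CT,B,0.0,1375.6,4.4,29.7,6.7,0.3
R06,PET,L,67.5,337.0,72.0,54.2,0.8,39.3
R06,PET,L_shell,9.9,336.8,28.4,41.3,1.5,4.6
R06,PET,B,1.9,337.0,10.5,26.2,2.5,1.0
R07,CT,L,6.1,1005.1,30.8,63.2,2.0,1.1
R07,CT,L_shell,0.0,1005.1,9.1,36.1,4.0,0.2
R07,CT,B,0.0,1005.1,3.2,21.9,6.8,0.2
R07,PET,L,30.6,316.0,54.5,55.0,1.0,12.4
R07,PET,L_shell,6.5,316.4,22.1,38.5,1.7,3.4
R07,PET,B,1.9,316.0,8.8,24.5,2.8,1.2
R08,CT,L,11.8,966.2,30.2,49.1,1.6,4.0
R08,CT,L_shell,0.1,966.2,8.3,27.7,3.3,0.2
R08,CT,B,0.0,966.2,3.5,18.5,5.3,0.2
R08,PET,L,22.5,304.0,39.9,41.2,1.0,11.8
R08,PET,L_shell,7.7,304.4,16.7,27.2,1.6,5.0
R08,PET,B,3.2,304.0,8.4,18.6,2.2,2.0
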