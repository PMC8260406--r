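kind,id,name,parent_phase_id,critical
phase,0,P0,,
phase,1,P1,,
phase,2,P2,,
phase,3,P3,,
phase,4,P4,,
phase,5,P5,,
phase,6,P6,,
phase,7,P7,,
phase,8,P8,,
phase,9,P9,,
phase,10,P10,,
step,0,S0,0,FALSE
step,1,S1,0,FALSE
step,2,S2,0,FALSE
step,3,S3,0,FALSE
step,4,S4,1,TRUE
step,5,S5,1,TRUE
step,6,S6,1,TRUE
step,7,S7,1,TRUE
step,8,S8,2,TRUE
step,9,S9,2,FALSE
step,10,S10,2,FALSE
step,11,S11,2,FALSE
step,12,S12,3,FALSE
step,13,S13,3,FALSE
step,14,S14,3,FALSE
step,15,S15,3,FALSE
step,16,S16,4,TRUE
step,17,S17,4,FALSE
step,18,S18,4,TRUE
step,19,S19,4,FALSE
step,20,S20,5,FALSE
step,21,S21,5,FALSE
step,22,S22,5,FALSE
step,23,S23,5,FALSE
step,24,S24,6,FALSE
step,25,S25,6,TRUE
step,26,S26,6,FALSE
step,27,S27,6,FALSE
step,28,S28,7,FALSE
step,29,S29,7,FALSE
step,30,S30,7,TRUE
step,31,S31,7,FALSE
step,32,S32,8,TRUE
step,33,S33,8,FALSE
step,34,S34,8,FALSE
step,35,S35,8,FALSE
step,36,S36,9,FALSE
step,37,S37,9,FALSE
step,38,S38,9,FALSE
step,39,S39,9,TRUE
step,40,S40,10,FALSE
step,41,S41,10,FALSE
step,42,S42,10,FALSE
step,43,S43,10,FALSE
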