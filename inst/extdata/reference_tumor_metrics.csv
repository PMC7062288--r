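# Printed per-tumor metric targets (main text): 17 d core diameter and rim
# size, infected/recruited ratio, and the diffuse tumor's treatment metrics.
tumor,metric,day,value_mm_or_ratio,treatment
nodular,d_c,17,2.3,none
nodular,d_r,17,0.6,none
intermediate,d_c,17,1.9,none
intermediate,d_r,17,1.0,none
diffuse,d_c,17,1.9,none
diffuse,d_r,17,2.1,none
nodular,I_R,17,0.17,none
intermediate,I_R,17,0.04,none
diffuse,I_R,17,0.55,none
diffuse,d_c,14,1.5,none
diffuse,d_r,14,1.4,none
diffuse,d_c,41,2.6,AP
diffuse,d_r,41,2.8,AP
diffuse,d_c,41,6.3,AM
diffuse,d_r,41,0.5,AM
diffuse,d_c,41,2.3,AP+AM
diffuse,d_r,41,1.3,AP+AM
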