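comparison,cost_int,cost_comp,ly_int,ly_comp,qaly_int,qaly_comp,printed_icer_ly,printed_icer_qaly,prose_delta_cost
BSC,107168,35090,4.05,1.88,3.06,1.24,33111,39610,72112
LDC,115537,53184,4.45,2.06,3.39,1.36,25953,30531,61929
SDC,106422,59725,3.96,1.49,2.94,0.98,18884,23804,NA
CCR,108605,43170,4.11,1.85,3.11,1.22,28891,34673,65436
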