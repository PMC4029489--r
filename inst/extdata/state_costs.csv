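arm,state,component,eur
AZA,on,pre_medication,0.70
AZA,on,administration,442.40
AZA,on,pharmacology,3028.14
AZA,on,follow_up,238.55
AZA,on,transfusions,926.07
AZA,on,concurrent_medication,37.90
AZA,on,routine_tests,237.49
AZA,off,follow_up,238.55
AZA,off,transfusions,926.07
AZA,off,concurrent_medication,54.72
AZA,off,routine_tests,62.63
AZA,off,annualized_ae_bsc,345.81
AZA,off,administration_bsc,0
AZA,aml,follow_up,233.33
AZA,aml,adverse_events,345.81
AZA,aml,concurrent_medication,132.18
AZA,aml,transfusions,1070.31
AZA,aml,routine_tests,70.24
BSC,on,pre_medication,0
BSC,on,administration,0
BSC,on,pharmacology,0
BSC,on,follow_up,238.55
BSC,on,transfusions,1070.31
BSC,on,concurrent_medication,54.72
BSC,on,routine_tests,62.63
BSC,off,follow_up,238.55
BSC,off,transfusions,1070.31
BSC,off,concurrent_medication,54.72
BSC,off,routine_tests,62.63
BSC,off,annualized_ae_bsc,345.81
BSC,off,administration_bsc,0
BSC,aml,follow_up,233.33
BSC,aml,adverse_events,345.81
BSC,aml,concurrent_medication,132.18
BSC,aml,transfusions,1070.31
BSC,aml,routine_tests,70.24
LDC,on,pre_medication,2.11
LDC,on,administration,380.20
LDC,on,pharmacology,48.38
LDC,on,follow_up,238.55
LDC,on,transfusions,1754.35
LDC,on,concurrent_medication,65.86
LDC,on,routine_tests,181.74
LDC,off,follow_up,238.55
LDC,off,transfusions,1754.35
LDC,off,concurrent_medication,54.72
LDC,off,routine_tests,62.63
LDC,off,annualized_ae_bsc,345.81
LDC,off,administration_bsc,0
LDC,aml,follow_up,233.33
LDC,aml,adverse_events,345.81
LDC,aml,concurrent_medication,132.18
LDC,aml,transfusions,1070.31
LDC,aml,routine_tests,70.24
SDC,on,pre_medication,0
SDC,on,administration,16344.02
SDC,on,pharmacology,790.41
SDC,on,follow_up,0
SDC,on,transfusions,2557.71
SDC,on,concurrent_medication,87.21
SDC,on,routine_tests,1073.74
SDC,off,follow_up,238.55
SDC,off,transfusions,2557.71
SDC,off,concurrent_medication,54.72
SDC,off,routine_tests,62.63
SDC,off,annualized_ae_bsc,345.81
SDC,off,administration_bsc,0
SDC,aml,follow_up,233.33
SDC,aml,adverse_events,345.81
SDC,aml,concurrent_medication,132.18
SDC,aml,transfusions,1070.31
SDC,aml,routine_tests,70.24
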