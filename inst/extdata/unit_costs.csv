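resource,eur,description
inpatient_day,742.91,Inpatient hospital stay per day (standard stay 28 days)
haematologist_visit,62.22,Standard MDS visit
nurse_visit,33.20,Average cost
biochemical_profile,44.03,Average cost
bone_marrow_aspirate,133.80,Average cost
full_blood_count,6.08,Average cost
platelet_transfusion,352.81,Per transfusion
blood_transfusion,353.23,Per transfusion
neutropenia,68,Medical visit and analytics
leucopenia,68,Medical visit and analytics
febrile_neutropenia,3735,DRG 722 simple pneumonia and pleurisy
pyrexia,3735,DRG 722 simple pneumonia and pleurisy
pneumonia,3735,DRG 722 simple pneumonia and pleurisy
sepsis,3728,ICD 205.00
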