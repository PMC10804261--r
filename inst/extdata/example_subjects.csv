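"subject_id","group","sex","age","illness_duration","n_antipsychotics","n_non_antipsychotics","n_mood_stabilizers","bprs_total","bnss_total","slof_total"
"res_001","residential","male",55,19,3,2,1,57,27,196
"con_001","control","female",52,,,,,,,
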