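"context","from_state","to_state","probability"
"mobile_cbt","MILD","NO_ANX",0.7
"mobile_cbt","MILD","MILD",0.288952702702703
"mobile_cbt","MILD","MOD",0.0110472972972973
"mobile_cbt","MOD","MILD",0.7
"mobile_cbt","MOD","MOD",0.251324257425743
"mobile_cbt","MOD","SEV",0.0381683168316832
"mobile_cbt","MOD","MOD_COMORB",0.0105074257425743
"mobile_cbt","SEV","MOD",0.7
"mobile_cbt","SEV","SEV",0.287128292268479
"mobile_cbt","SEV","SEV_COMORB",0.0128717077315208
"status_quo","NO_ANX","NO_ANX",0.9418
"status_quo","NO_ANX","MILD",0.0582
"status_quo","MILD","NO_ANX",0.112
"status_quo","MILD","MILD",0.8553
"status_quo","MILD","MOD",0.0327
"status_quo","MOD","MILD",0.192
"status_quo","MOD","MOD",0.6769
"status_quo","MOD","SEV",0.1028
"status_quo","MOD","MOD_COMORB",0.0283
"status_quo","SEV","MOD",0.0584
"status_quo","SEV","SEV",0.9012
"status_quo","SEV","SEV_COMORB",0.0404
"status_quo","MOD_COMORB","MOD",0.1309
"status_quo","MOD_COMORB","MOD_COMORB",0.7714
"status_quo","MOD_COMORB","SEV_COMORB",0.0977
"status_quo","SEV_COMORB","SEV",0.0654
"status_quo","SEV_COMORB","MOD_COMORB",0.0412
"status_quo","SEV_COMORB","SEV_COMORB",0.8934
"status_quo","DEAD","DEAD",1
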