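"state","physician_visits","er_visits","hospitalizations","disability_days"
"NO_ANX",3.6,0.07,0.018,1
"MILD",5.5,0.15,0.036,4
"MOD",9,0.36,0.11,11
"SEV",14.5,0.65,0.22,22
"MOD_COMORB",20,0.91,0.36,30
"SEV_COMORB",25.5,1.45,0.65,45
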