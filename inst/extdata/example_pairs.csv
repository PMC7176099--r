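study,ro,no,rr,nr,pm_belief
ex-001,0.42,47,0.19,61,0.6
ex-002,0.63,24,0.52,35,0.75
ex-003,-0.28,90,-0.05,90,0.3
ex-004,0.51,33,0.12,58,0.45
ex-005,0.35,68,0.33,80,0.7
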