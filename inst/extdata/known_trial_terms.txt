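# Preferred terms reported as adverse events in the pivotal phase III trial
# (reconstruction from published per-term annotations; one PT per line)
Nausea
Fatigue
Nasopharyngitis
Blood creatinine increased
Blood pressure abnormal
Gout
Arthralgia
Pruritus
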