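# Preferred terms listed as adverse reactions in the drug insert
# (reconstruction from published per-term annotations; one PT per line)
Anemia
Edema peripheral
Blood pressure decreased
Glomerular filtration rate decreased
Hepatic enzyme increased
Blood potassium increased
Dizziness
Hypotension
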