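dimension,category,n,pct
sex,female,219,43.50
sex,male,277,55.00
sex,unknown,8,1.60
age,<18,2,0.40
age,18-45,168,33.33
age,>45,205,40.67
age,unknown,129,25.60
outcome,hospitalization,13,2.60
outcome,other_ime,31,6.20
outcome,unknown,460,91.30
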