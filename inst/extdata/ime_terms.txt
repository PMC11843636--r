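# Synthetic miniature stand-in for the EMA Important Medical Events list
# (the full EMA list is not redistributable here; supply your own for real use)
Loss of consciousness
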