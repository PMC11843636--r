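# Synthetic miniature stand-in for the EMA Designated Medical Events list
# (empty by default; supply your own for real use)
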