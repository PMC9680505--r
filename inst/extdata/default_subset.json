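["R", "G", "B", "H", "S", "a", "b", "GE", "M", "Y", "Cb", "Cr", "I", "Q"]
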