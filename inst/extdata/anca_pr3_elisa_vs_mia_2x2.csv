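elisa,positive,negative
positive,98,25
negative,18,451
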