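aaeacb9efbcf4865059a20d2814c2b3e  psychopsid_specimens.tsv
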