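# element x y z q sigma epsilon
Ar                  0                  0                  0                  0 3.3999999999999999                  1
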