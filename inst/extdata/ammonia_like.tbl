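# element x y z q sigma epsilon
N                  0                  0                  0 -0.90000000000000002               3.25 0.71099999999999997
H 0.90973437607876606                  0 -0.44331407036160964 0.29999999999999999 1.0700000000000001 0.065699999999999995
H -0.45486718803938281 0.78785308038019775 -0.44331407036160964 0.29999999999999999 1.0700000000000001 0.065699999999999995
H -0.45486718803938342 -0.78785308038019752 -0.44331407036160964 0.29999999999999999 1.0700000000000001 0.065699999999999995
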