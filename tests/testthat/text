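#!places p1 p2 p3 p4
t1: 3*p1 + 3*p2 + 3*p3 + 2*p4 => 2*p1 + 2*p3 + p4
t2: p1 + 2*p2 + 2*p3 => 3*p2 + 2*p4
t3: 3*p2 => 3*p1 + p4
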