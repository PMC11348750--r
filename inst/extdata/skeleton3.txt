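# minimal hand-written skeleton: two stem vertices and one side vertex
pitch 0.44
v 1 0.0 0.0 0.0 2.0
v 2 0.0 0.0 -4.0 1.8
v 3 5.0 0.0 -2.0 0.9
e 1 2
e 2 3
stem 1 2
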