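item,answer
q1,5
q1,5
q1,5
q1,5
q1,4
q1,4
q1,4
q1,4
q1,4
q2,5
q2,5
q2,5
q2,5
q2,4
q2,4
q2,4
q2,4
q2,2
q3,5
q3,5
q3,4
q3,4
q3,4
q3,4
q3,4
q3,4
q3,4
q4,5
q4,5
q4,5
q4,4
q4,4
q4,3
q4,3
q4,3
q4,2
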