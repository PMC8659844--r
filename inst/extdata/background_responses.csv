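item,answer
q1,60
q1,60
q1,50
q1,50
q1,50
q1,40
q1,35
q1,30
q1,10
q2,5
q2,4
q2,4
q2,4
q2,4
q2,4
q2,3
q2,3
q2,3
q3,4
q3,4
q3,4
q3,3
q3,3
q3,3
q3,3
q3,2
q3,2
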