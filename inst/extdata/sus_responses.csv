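item,answer
q1,5
q1,4
q1,4
q1,4
q1,4
q1,4
q1,4
q1,3
q1,3
q2,4
q2,4
q2,3
q2,2
q2,2
q2,2
q2,2
q2,2
q2,1
q3,5
q3,5
q3,4
q3,4
q3,4
q3,4
q3,4
q3,3
q3,3
q4,4
q4,4
q4,3
q4,3
q4,3
q4,2
q4,2
q4,2
q4,1
q5,5
q5,5
q5,5
q5,4
q5,4
q5,4
q5,4
q5,4
q5,3
q6,3
q6,3
q6,2
q6,2
q6,2
q6,2
q6,1
q6,1
q6,1
q7,4
q7,4
q7,4
q7,3
q7,3
q7,3
q7,3
q7,3
q7,3
q8,2
q8,2
q8,2
q8,2
q8,2
q8,1
q8,1
q8,1
q8,1
q9,4
q9,4
q9,4
q9,4
q9,4
q9,4
q9,4
q9,3
q9,2
q10,5
q10,3
q10,2
q10,2
q10,2
q10,2
q10,1
q10,1
q10,1
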