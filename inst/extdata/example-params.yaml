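# standard worked-example parameter set
d: 0.1
c: 0.9
p: 0.5
tau: 0.5
mu_R: 1.0
mu_P: 0.1
q_HR: 1.0
q_LR: 0.1
q_HP: 1.0
q_LP: 0.1
n: 2
Q: 0.5
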