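id,L1,L2,L3,L4,L5,L6
f_high,0,2,1,2,0,1
f_low,2,0,1,0,2,1
m_high,1,2,0,2,1,0
m_low,2,0,2,0,1,2
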