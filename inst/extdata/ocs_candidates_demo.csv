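id,gebv,pool
f_high,2.0,female
f_low,1.0,female
m_high,3.0,male
m_low,0.5,male
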