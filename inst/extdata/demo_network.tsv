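tf1	g1
tf1	g2
tf2	g1
tf2	g2
tf3	g1
tf3	g2
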