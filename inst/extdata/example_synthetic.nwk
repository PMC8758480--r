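(((hg38:0.01,panTro:0.01):0.025,rheMac:0.035):0.24,mm10:0.275);
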