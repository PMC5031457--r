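true,Tsik,Tsik-ek
Tsik,90.5,9.5
Tsik-ek,24.5,75.5
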