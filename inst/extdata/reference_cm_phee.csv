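true,Phee-2,Phee-3,Phee-4
Phee-2,70.4,14.8,14.8
Phee-3,19.8,46.2,34.0
Phee-4,9.7,39.1,51.2
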