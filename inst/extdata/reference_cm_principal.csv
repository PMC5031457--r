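true,Alarm,Chirp,Loud-shrill,Phee,Seep,Trill,Tsik,Twitter
Alarm,78.4,3.9,5.9,4.3,5.7,1.6,0.2,0.0
Chirp,0.0,89.5,0.0,0.1,0.0,0.0,1.0,9.4
Loud-shrill,4.7,0.0,75.3,4.3,0.0,15.7,0.0,0.0
Phee,4.1,1.6,5.9,83.0,0.0,0.0,0.0,5.4
Seep,4.3,0.0,0.0,0.0,90.6,0.0,5.1,0.0
Trill,0.7,0.0,19.2,0.9,0.0,74.0,0.0,5.2
Tsik,2.5,4.4,0.0,0.0,8.3,0.0,77.5,7.3
Twitter,0.0,7.0,0.4,0.5,0.0,0.0,0.0,92.1
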