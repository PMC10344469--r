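tissue,B,S,W,M,F,a,b,ri
brain,0.03,0.65,0.75,0,0.05,538700,1.611,1.37
bone,0.004,0.65,0.35,0,0.25,1967,0.716,1.55
blubber_skin,0.006,0.98,0.1,0.00002,0.2,1546,0.8038,1.45
muscle,0.04,0.65,0.76,0,0.1,4108,0.926,1.37
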