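time_s,velocity,acceleration,turning_angle,player_id,match_id,position
1469.0,1.00,0.50,5,p01,m01,hooker
1469.1,1.20,0.30,20,p01,m01,hooker
1469.2,0.80,0.00,30,p01,m01,hooker
1469.3,1.00,0.10,5,p01,m01,hooker
1469.4,1.10,0.90,2,p01,m01,hooker
1469.5,1.30,0.40,60,p01,m01,hooker
1469.6,0.90,0.05,120,p01,m01,hooker
1469.7,0.70,-0.50,150,p01,m01,hooker
1469.8,0.60,-1.00,95,p01,m01,hooker
1469.9,0.50,-0.30,15,p01,m01,hooker
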