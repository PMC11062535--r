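time_s,velocity_band,acceleration_band,turning_band,char
1469.0,Walk,Acceleration,Straight,i
1469.1,Walk,Acceleration,Acute-change,j
1469.2,Walk,Neutral,Acute-change,f
1469.3,Walk,Neutral,Straight,e
1469.4,Walk,Acceleration,Straight,i
1469.5,Walk,Acceleration,Large-change,k
1469.6,Walk,Neutral,Backwards,h
1469.7,Walk,Deceleration,Backwards,d
1469.8,Walk,Deceleration,Backwards,d
1469.9,Walk,Deceleration,Acute-change,b
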