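structure,category,Lateral transgluteal,MIS anterior,MIS anterolateral,MIS 2-incision,MIS posterior
M. piriformis,muscle release,1,0,0,0,3
M. gemellus superior,muscle release,1,1,0,0,5
M. gemellus inferior,muscle release,1,1,0,2,5
M. obturator internus,muscle release,1,1,0,0,5
Gluteus superior nerve,transected nerve,1,0,3,0,0
Lateral femoral cutaneous nerve,transected nerve,0,1,0,1,0
Sciatic nerve,transected nerve,0,0,0,0,0
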