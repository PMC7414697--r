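category,grade,total,train,val,test
No DR,0,31447,23585,3145,4717
Mild DR,1,1264,948,126,190
Moderate DR,2,6822,5117,682,1023
Severe DR,3,230,172,23,35
Proliferative DR,4,683,512,68,103
Ungradable,NA,6419,NA,NA,NA
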