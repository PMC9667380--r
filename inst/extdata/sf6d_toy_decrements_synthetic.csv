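dimension,level,decrement
PF,1,0
PF,2,0.05
PF,3,0.10
RL,1,0
RL,2,0.05
RL,3,0.10
RL,4,0.15
SF,1,0
SF,2,0.05
SF,3,0.10
SF,4,0.15
SF,5,0.20
PAIN,1,0
PAIN,2,0.05
PAIN,3,0.10
PAIN,4,0.15
PAIN,5,0.20
MH,1,0
MH,2,0.05
MH,3,0.10
MH,4,0.15
MH,5,0.20
VIT,1,0
VIT,2,0.05
VIT,3,0.10
VIT,4,0.15
VIT,5,0.20
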