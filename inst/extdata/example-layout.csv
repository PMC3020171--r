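channel,x,y,label
1,0,0,C3-posterior
2,1,0,C3
3,2,0,C3-anterior
4,0,1,dlPFC-inf
5,1,1,dlPFC
6,2,1,M1
7,0,2,Broca-inf
8,1,2,Broca
9,2,2,premotor
10,3,0,parietal
11,3,1,M1-lateral
12,3,2,premotor-lateral
13,0,3,frontal-inf
14,1,3,frontal
15,2,3,frontal-sup
16,3,3,frontal-lateral
17,4,0,temporal
18,4,1,central
19,4,2,BA9
20,4,3,BA8
21,5,0,posterior
22,5,1,inactive-ref
23,5,2,lateral
24,5,3,superior
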