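species,CH,LDMC,LS,LDW,SLA,LNC,LA,LFW,LCC
AdeLeu,358,17.1,3,116.5,21.4,3.2,2440.2,701.6,46.7
CarRes,24,26.0,2,3.7,16.2,3.6,58.2,14.4,45.4
CerUni,16,16.2,3,2.2,37.6,3.4,84.2,13.9,41.8
GeuRep,75,27.4,6,67.4,8.3,3.0,566.4,249.8,47.5
GnaSup,12,37.3,4,0.7,25.1,1.9,17.5,2.0,47.7
HieAlp,16,16.2,3,8.0,15.2,1.6,121.8,32.4,46.0
LeuAlp,33,16.4,4,2.4,18.2,2.6,42.4,15.2,44.7
LuzAlp,152,17.9,4,13.9,29.1,2.9,388.2,77.3,46.9
OxyDig,76,10.0,4,12.3,29.5,4.7,353.5,123.9,45.4
PoaAlp,36,34.3,3,29.6,11.1,1.3,328.6,86.6,45.8
RanGla,46,14.2,2,18.8,14.1,1.7,262.1,132.0,44.3
SalHer,14,33.2,6,7.6,15.2,2.0,165.0,22.9,47.4
SaxBry,5,32.4,4,0.2,15.3,1.8,2.8,0.7,44.0
SaxOpp,6,25.5,4,0.3,15.7,1.8,4.0,1.0,46.8
SedAlp,15,7.8,2,0.4,14.2,1.1,5.7,5.1,41.5
VerAlp,46,18.0,2,2.1,28.6,1.6,57.9,11.9,47.4
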