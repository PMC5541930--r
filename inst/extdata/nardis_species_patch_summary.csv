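species,frequency,MPS,MPS_sd,CA,MSI,MSI_sd,NP,TE
AdeLeu,2,11,NA,11,1.05,NA,1,14
CarRes,11,9,4,70,1.09,0.07,8,100
CerUni,43,55,151,2318,1.23,0.23,42,1188
GeuRep,46,38,41,2717,1.19,0.10,72,1928
GnaSup,7,11,7,128,1.16,0.07,12,172
HieAlp,4,15,15,30,1.21,0.05,2,34
LeuAlp,70,40,237,6880,1.72,0.20,173,4018
LuzAlp,22,110,222,2086,1.25,0.20,19,754
OxyDig,59,30,38,6206,1.26,0.23,209,5454
PoaAlp,96,24,30,7476,1.17,0.12,310,6456
RanGla,13,10,7,177,1.10,0.07,17,228
SalHer,15,307,458,3682,1.34,0.35,12,1042
SaxBry,72,95,238,30378,1.28,0.27,320,13324
SaxOpp,39,69,114,5702,1.25,0.17,83,3006
SedAlp,33,7,6,644,1.13,0.10,87,1010
VerAlp,54,15,14,2013,1.17,0.13,134,2260
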