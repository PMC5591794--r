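structure,degree,configuration,PRINGLE,VOTE,NOHL,PTLTBE
N,0,,X,X,"N1,N2",X
N,1,,X,X,N3,X
N,2,,X,X,N4,X
V,0,AP,G1,Vk0AP,"OAP1,OAP2",P1
V,1,AP,G1,Vk1AP,OAP3,P2
V,2,AP,G2,Vk2AP,OAP4,P2
V,0,L,G1,Vk0L,"Ot1,Ot2",-
V,1,L,G1,Vk1L,Ot3,-
V,2,L,G2,Vk2L,Ot4,-
V,0,C,G1,Vk0C,"OC1,OC2",P1
V,1,C,G1,Vk1C,OC3,P3
V,2,C,G2,Vk2C,OC4,P3
Ts,0,L,G1,Ok0L,-,T1
Ts,1,L,G1,Ok1L,-,T2
Ts,2,L,G2,Ok2L,"Ts3,Ts4",T3
O,0,AP,-,-,-,-
O,1,AP,-,-,-,-
O,2,AP,"G3,G4",-,-,-
O,0,L,-,Ok0L,"Ot1,Ot2",L1
O,1,L,-,Ok1L,Ot3,L2
O,2,L,"G3,G4",Ok2L,Ot4,L3
O,0,C,-,-,"OC1,OC2",-
O,1,C,-,-,OC3,-
O,2,C,"G3,G4",-,OC4,-
Tb,0,AP,G5,Tk0AP,"HAP1,HAP2",Tb1
Tb,1,AP,G5,Tk1AP,HAP3,Tb2
Tb,2,AP,G5,Tk2AP,HAP4,Tb3
Tb,0,L,G5,-,"HL1,HL2",-
Tb,1,L,G5,-,HL3,-
Tb,2,L,G5,-,HL4,-
Tb,0,C,G5,-,"HC1,HC2",-
Tb,1,C,G5,-,HC3,-
Tb,2,C,G5,-,HC4,-
E,0,AP,G5,Ek0AP,LN,E1
E,1,AP,G5,Ek1AP,LP,E2
E,2,AP,G5,Ek2AP,LP,E2
E,0,L,G5,Ek0L,LN,-
E,1,L,G5,Ek1L,LP,-
E,2,L,G5,Ek2L,LP,-
L,0,,X,X,LN,X
L,1,,X,X,LP,X
L,2,,X,X,LP,X
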