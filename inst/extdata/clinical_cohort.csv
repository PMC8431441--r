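patient_id,outcome,nodal,n_stage,t_stage,stage,grade,er,pr,tils_percent
P01,ND,N0,N0,T1c,IA,G2,pos,pos,12.9
P02,ND,N0,N0,T1c,IA,G2,pos,pos,
P03,ND,N0,N0,T1c,IA,G2,pos,pos,8.6
P04,ND,N0,N0,T1c,IA,G2,pos,pos,
P05,ND,N0,N0,T1c,IA,G2,pos,neg,57.1
P06,ND,N0,N0,T1c,IA,G3,pos,neg,
P07,ND,N0,N0,T1c,IA,G3,neg,neg,47.2
P08,ND,N0,N0,T1c,IA,G3,neg,neg,13.8
P09,ND,N0,N0,T1c,IA,G3,neg,neg,
P10,ND,N0,N0,T1c,IA,G3,neg,neg,13.1
P11,ND,N0,N0,T1c,IA,G3,neg,neg,
P12,ND,N0,N0,T1c,IA,G3,neg,neg,
P13,ND,N0,N0,T2,IIA,G3,neg,neg,
P14,ND,N0,N0,T2,IIA,G3,neg,neg,
P15,ND,N0,N0,T2,IIA,G3,neg,neg,
P16,ND,N0,N0,T2,IIA,G3,neg,neg,
P17,ND,N0,N0,T2,IIA,G3,neg,neg,
P18,ND,N0,N0,T2,IIA,G3,neg,neg,7
P19,ND,N0,N0,T2,IIA,G3,neg,neg,
P20,ND,N+,N1,T1c,IIA,G2,pos,pos,20.3
P21,ND,N+,N1,T1c,IIA,G2,pos,pos,
P22,ND,N+,N1,T1c,IIA,G2,pos,pos,
P23,ND,N+,N1,T1c,IIB,G2,pos,neg,
P24,ND,N+,N1,T1c,IIB,G2,pos,neg,18.3
P25,ND,N+,N1,T2,IIB,G2,pos,neg,4.3
P26,ND,N+,N1,T2,IIB,G3,pos,neg,10.3
P27,ND,N+,N1,T2,IIB,G3,neg,neg,67.1
P28,ND,N+,N1,T2,IIB,G3,neg,neg,11.6
P29,ND,N+,N1,T2,IIB,G3,neg,neg,
P30,ND,N+,N2,T2,IIB,G3,neg,neg,
P31,ND,N+,N2,T2,IIIA,G3,neg,neg,4.5
P32,ND,N+,N2,T2,IIIA,G3,neg,neg,
P33,ND,N+,N3,T2,IIIC,G3,neg,neg,
P34,ND,N+,N3,T2,IIIC,G3,neg,neg,23.4
P35,ND,N+,N3,T2,IIIC,G3,neg,neg,
P36,ND,N+,N3,T2,IIIC,G3,neg,neg,5.3
P37,ND,N+,N3,T2,IIIC,G3,neg,neg,3.8
P38,ND,N+,N3,T2,IIIC,G3,neg,neg,
P39,PD,N0,N0,T1c,IA,G2,pos,pos,
P40,PD,N0,N0,T1c,IA,G2,pos,pos,
P41,PD,N0,N0,T1c,IA,G2,pos,pos,9.5
P42,PD,N0,N0,T2,IIA,G2,pos,pos,
P43,PD,N0,N0,T2,IIA,G3,neg,neg,16.9
P44,PD,N0,N0,T2,IIA,G3,neg,neg,7.5
P45,PD,N0,N0,T2,IIA,G3,neg,neg,1
P46,PD,N0,N0,T2,IIB,G3,neg,neg,4.1
P47,PD,N+,N1,T1c,IIA,G2,pos,pos,14
P48,PD,N+,N1,T1c,IIA,G2,pos,pos,11.6
P49,PD,N+,N1,T1c,IIB,G2,pos,pos,3
P50,PD,N+,N1,T1c,IIB,G2,pos,pos,6.3
P51,PD,N+,N2,T1c,IIB,G2,pos,pos,1
P52,PD,N+,N2,T2,IIIA,G2,pos,pos,
P53,PD,N+,N2,T2,IIIA,G3,pos,pos,
P54,PD,N+,N2,T2,IIIA,G3,pos,pos,38.5
P55,PD,N+,N2,T2,IIIA,G3,pos,neg,17.6
P56,PD,N+,N2,T2,IIIA,G3,pos,neg,10.3
P57,PD,N+,N2,T2,IIIA,G3,neg,neg,13.1
P58,PD,N+,N3,T2,IIIC,G3,neg,neg,4.9
P59,PD,N+,N3,T2,IIIC,G3,neg,neg,7.8
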