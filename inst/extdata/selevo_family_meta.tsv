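family	parent_family	selenoprotein_subfamily	notes
GPx1		TRUE	
GPx2		TRUE	
GPx3		TRUE	
GPx4		TRUE	
TR1		TRUE	
TR3		TRUE	
Dio1		TRUE	
Dio2		TRUE	
Dio3		TRUE	
SelH		TRUE	
SelI		TRUE	
SelJ		TRUE	
SelK		TRUE	
SelL		TRUE	
SelM		TRUE	
SelN		TRUE	
SelO		TRUE	
SelP		TRUE	
SelPb		TRUE	
MsrB1		TRUE	
SelS		TRUE	
SelT1		TRUE	
SelU1		TRUE	
SelW1		TRUE	
SelW2		TRUE	
Sep15		TRUE	
Fep15		TRUE	Sec in cartilaginous and bony fish; Cys homolog in frog
SPS2a		TRUE	
GPx1b	GPx1	TRUE	
GPx3b	GPx3	TRUE	
GPx4b	GPx4	TRUE	
Dio3b	Dio3	TRUE	intronless, like Dio3
SelT2	SelT1	TRUE	
MsrB1b	MsrB1	TRUE	
SelU1c	SelU1	TRUE	
SelO2	SelO	TRUE	
SelT1b	SelT1	TRUE	
SelW2b	SelW2	TRUE	
SelJ2	SelJ	TRUE	
SelU1b	SelU1	TRUE	
SelW2c	SelW2	TRUE	Sec replaced by arginine (CGA) in pufferfish
TGR	TR1	TRUE	
SPS2b	SPS2a	TRUE	intronless retrogene of SPS2a
GPx6	GPx3	TRUE	
SelV	SelW1	TRUE	
GPx5	GPx3	FALSE	Cys in all placentals; converted at birth
GPx4b2	GPx4b	FALSE	Cys copy of GPx4b in medaka; converted at birth
Rdx12	SelW2	FALSE	Cys homolog of SelW2 in all tetrapods; converted at birth
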