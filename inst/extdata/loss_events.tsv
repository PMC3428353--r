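# Reference table of inferred canonical-cysteine loss events in insect
# odorant-binding proteins (wasp, honeybee, fly, mosquito, beetle, aphid,
# louse and related families), as published for the Nasonia vitripennis
# OBP analysis: 22 parsimony-inferred events, one row per event.
# Suffixes a/b on double-domain gene names denote the first/second domain.
# lost_set: cysteines lost in the event; affected_genes: descendant genes
# lacking them.
lost_set	event_id	bond_pair	affected_genes
C1	1	no	NvitOBP31
C1	2	no	NvitOBP64,DmelObp59a
C2	1	no	AgamOBP38b
C2	2	no	AgamOBP42a
C5	1	no	NvitOBP38b,NvitOBP39b,NvitOBP40b,NvitOBP41b,NvitOBP42b,NvitOBP44b,NvitOBP45b
C5	2	no	ApisOBP11
C6	1	no	DmelOBP73a
C6	2	no	AcerASP4
C1/C3	1	yes	AgamOBP34b,AgamOBP35b,AgamOBP36b,AgamOBP37b
C2/C5	1	yes	NvitOBP27,NvitOBP56,NvitOBP58,NvitOBP59,NvitOBP60,NvitOBP61,NvitOBP62
C2/C5	2	yes	NvitOBP38a,NvitOBP39a,NvitOBP40a,NvitOBP41a,NvitOBP42a,NvitOBP43,NvitOBP44a,NvitOBP45a,NvitOBP46a
C2/C5	3	yes	DmelOBP8a,DmelOBP99c,DmelOBP99d
C2/C5	4	yes	DmelOBP44a
C2/C5	5	yes	AgamOBP39b
C2/C5	6	yes	LtesOBP8
C2/C5	7	yes	AmelOBP14,AmelOBP15,AmelOBP16,AmelOBP17,AmelOBP18,AmelOBP19,AmelOBP20,AmelOBP21
C2/C5	8	yes	TcasOBP02,TcasOBP03,TcasOBP04,TcasOBP05,TcasOBP06,TcasOBP07,TcasOBP08,TcasOBP09,TcasOBP10,TcasOBP11,TcasOBP12,TcasOBP13,TcasOBP14,TcasOBP15,TcasOBP22,TcasOBP23,TcasOBP24,TcasOBP33,TcasOBP34,TcasOBP44
C4/C6	1	yes	AgamOBP40a
C4/C6	2	yes	AgamOBP45b
C2/C6	1	no	NvitOBP69
C5/C6	1	no	AgamOBP65
C4/C5/C6	1	no	AgamOBP16
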