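rank	compound_id	pubchem_cid	name	degree
1	BB5	60961	Adenosine	75
2	RG6	107848	Geniposide	56
3	PL3	21631108	Moudanpioside F	52
4	BB1	135398635	Guanosine	48
5	PS3	21631103	Mudanpioside D	45
6	PS4	19844	Methyl vanillate	42
7	PL2	8814958	1-O-beta-D-Glucopyranosyl-paeonisuffron	40
8	PL1	71452333	8-Debenzoylpaeoniflorin	32
9	BB2	5960	Aspartic acid	30
10	RG7	21637711	Rehmapicroside	28
11	PL5	442534	Paeoniflorin	28
12	PS1	10592506	Mudanoside A	28
13	PS2	11092	Paeonol	28
14	BB3	145742	Proline	26
15	RG1	91458	Aucubin	26
16	RG5	159278	Salidroside	23
17	PL4	21631105	Oxypaeoniflora	23
18	RG3	91520	Catalpol	20
19	RG2	158144	8-Epiloganic acid	17
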