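system	location	abbrev	N	He	pS	S
Au Sable River	Foote Dam Pond	FDP	21	0.190	0	1530
Au Sable River	Cooke Dam Pond	CDP	25	0.189	0	1617
Au Sable River	Five Channels Pond	FCP	25	0.196	0	1780
Cheboygan River	Burt Lake	BTL	20	0.195	1	1577
Cheboygan River	Mullett Lake	MLL	25	0.193	1	1609
Flint River	Below Mott Lake	BML	25	0.137	0	822
Flint River	Mott Lake	MTL	25	0.137	0	820
Flint River	Holloway Reservoir	HWR	25	0.116	0	762
Great Lakes	Alpena	ALP	25	0.191	1	1754
Great Lakes	Cheboygan River mouth	CBR	25	0.200	0	1847
Great Lakes	Grand Traverse Bay	GTB	25	0.174	1	1469
Great Lakes	Lake Erie	LKE	25	0.202	3	1913
Great Lakes	Lake St. Clair	STC	25	0.206	3	1807
Great Lakes	Little Traverse Bay	LTB	25	0.193	3	1695
Great Lakes	Muskegon River	MGL	24	0.190	4	1545
Great Lakes	Pentwater Lake	PWL	25	0.181	2	1484
Great Lakes	Rogers City	RGC	25	0.202	8	1849
Great Lakes	Saginaw Bay	SAB	25	0.199	1	1728
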