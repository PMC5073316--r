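gene	direction	start	end	size	anticodon	start_codon	stop_codon	intergenic
trnM	F	1	68	68	CAT			2
trnI	F	71	135	65	GAT			-3
trnQ	R	133	201	69	TTG			50
nad2	F	252	1266	1015		ATT	T	-3
trnW	F	1264	1332	69	TCA			-9
trnC	R	1324	1388	65	GCA			5
trnY	R	1394	1462	67	GTA			3
cox1	F	1466	2996	1531		CGA	T	0
trnL2(UUR)	F	2997	3065	69	TAA			0
cox2	F	3066	3747	682		ATG	T	0
trnK	F	3748	3820	73	CTT			16
trnD	F	3837	3899	63	GTC			0
atp8	F	3900	4061	162		ATT	TAA	-7
atp6	F	4055	4728	674		ATG	TAA	3
cox3	F	4732	5517	786		ATG	TAA	2
trnG	F	5520	5588	69	TCC			0
nad3	F	5589	5942	354		ATT	TAA	6
trnA	F	5949	6018	70	TGC			36
trnR	F	6055	6121	67	TCG			1
trnN	F	6123	6196	74	GTT			1
trnS1(AGN)	F	6198	6263	66	GCT			10
trnE	F	6274	6343	70	TTC			-2
trnF	R	6342	6410	69	GAA			7
nad5	R	6418	8136	1719		ATC	TAA	15
trnH	R	8152	8219	68	GTG			0
nad4	R	8220	9555	1336		ATG	T	0
nad4L	R	9556	9839	284		ATA	A	24
trnT	F	9864	9927	64	TGT			0
trnP	R	9928	9993	66	TGG			8
nad6	F	10002	10520	519		ATA	TAA	4
cob	F	10525	11674	1150		ATG	T	0
trnS2(UCN)	F	11675	11744	70	TGA			-5
nad1	R	11770	12708	939		ATG	TAA	0
trnL1(CUN)	R	12709	12779	71	TAG			0
rrnL	R	12780	14138	1359				0
trnV	R	14139	14203	65	TAC			0
rrnS	R	14204	14995	792				0
A+T-rich region		14996	15396	401				
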