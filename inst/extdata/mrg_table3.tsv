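ko	gene_symbol	metal_group	metals	mechanism	specific	source
K03327	TC.MATE	Al	Al	Export	FALSE	KEGG
K17686	copA	Cu	Cu	Export	TRUE	BacMet
K01533	copB	Cu	Cu	Export	TRUE	BacMet
K19591	cueR	Cu	Cu	Regulation	TRUE	BacMet
K22552	mmcO	Cu	Cu	Biochemical Transformation	TRUE	KEGG
K07665	copR	Cu	Cu	Regulation	TRUE	KEGG
K07787	cusA	Cu	Cu,Ag	Export	FALSE	KEGG
K07798	cusB	Cu	Cu,Ag	Export	FALSE	KEGG
K07810	cusF	Cu	Cu,Ag	Export	FALSE	KEGG
K07213	copZ	Cu	Cu	Export	TRUE	BacMet
K07243	ftr1	Fe	Fe,Pb	Import	FALSE	BacMet
K13283	fieF	Fe	Fe,Zn,Co,Cd,Ni	Export	FALSE	BacMet
K02012	fbpA	Fe	Fe,Ga	Import	FALSE	BacMet
K02011	fbpB	Fe	Fe,Ga	Import	FALSE	BacMet
K18683	rus	Fe	Fe,Cu	Biochemical Transformation	FALSE	literature
K03711	fur	Fe	Fe	Regulation	TRUE	KEGG
K00522	fth1	Fe	Fe	Intracellular Accumulation	TRUE	KEGG
K02217	ftnA	Fe	Fe,Cu,Mn	Intracellular Accumulation	FALSE	BacMet
K03594	bfr	Fe	Fe	Intracellular Accumulation	TRUE	KEGG
K23242	mntP	Mn	Mn	Export	TRUE	BacMet
K03322	mntH	Mn	Mn,Zn,Fe	Import	FALSE	BacMet
K11924	mntR	Mn	Mn,Fe,Zn,Cd,Co	Regulation	FALSE	KEGG
K01534	zntA	Zn	Zn,Cd,Co,Pb	Export	FALSE	BacMet
K09815	znuA	Zn	Zn	Import	TRUE	KEGG
K09816	znuB	Zn	Zn	Import	TRUE	KEGG
K09817	znuC	Zn	Zn	Import	TRUE	KEGG
K15726	czcA	Zn	Co,Zn,Cd,Ni	Export	FALSE	BacMet
K15727	czcB	Zn	Co,Zn,Cd,Ni	Export	FALSE	BacMet
K15725	czcC	Zn	Co,Zn,Cd,Ni	Export	FALSE	BacMet
K16264	czcD	Zn	Co,Zn,Cd,Ni	Export	FALSE	BacMet
K21903	cadC	Zn	Cd,Bi,Zn,Pb	Regulation	FALSE	BacMet
K03709	troR	Zn	Zn,Mn,Fe	Regulation	FALSE	BacMet
K15584	nikA	Ni	Ni	Import	TRUE	KEGG
K15586	nikC	Ni	Ni	Import	TRUE	KEGG
K07785	ncrA	Ni	Ni,Co,Cd,Zn,Fe	Export	FALSE	BacMet
K08970	ncrC	Ni	Ni,Co,Cd,Zn,Fe	Export	FALSE	BacMet
K03325	acr3	As	As	Export	TRUE	KEGG
K01551	arsA	As	As	Export	TRUE	KEGG
K03893	arsB	As	As	Export	TRUE	KEGG
K03741	arsC	As	As	Biochemical Transformation	TRUE	KEGG
K22547	arsC_HAC1	As	As	Biochemical Transformation	TRUE	KEGG
K08355	aioB	As	As	Biochemical Transformation	TRUE	KEGG
K02038	pstA	As	As,P	Biochemical Transformation	FALSE	BacMet
K02036	pstB	As	As,P	Biochemical Transformation	FALSE	BacMet
K02037	pstC	As	As,P	Biochemical Transformation	FALSE	BacMet
K02040	pstS	As	As,P	Biochemical Transformation	FALSE	BacMet
K03892	arsR	As	As	Regulation	TRUE	KEGG
K09043	acr1	As	As	Regulation	TRUE	KEGG
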