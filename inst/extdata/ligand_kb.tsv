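receptor_symbol	receptor_accession	ligand_name	ligand_available	notes
NTRK2	Q16620	BDNF	TRUE	TRKB; supplementation panel; working concentration 50 ng/mL
CNTFR	P26992	CNTF	TRUE	supplementation panel; working concentration 50 ng/mL
GFRA1	P56159	GDNF	TRUE	supplementation panel; working concentration 50 ng/mL
GFRA2	O00451	NRTN	TRUE	neurturin; supplementation panel; working concentration 50 ng/mL
GFRA3	O60609	PSPN	TRUE	persephin; supplementation panel; canonical GFRA3 ligand is artemin
NTRK1	P04629	NGF	FALSE	not in the study supplement panel
NTRK3	Q16288	NT3	FALSE	TRKC; target of the conventional BDNF+NT3 medium
NGFR	P08138	NGF	FALSE	p75 pan-neurotrophin receptor
RET	P07949	GDNF	FALSE	signalling co-receptor of the GFRA family
LIFR	P42702	LIF	FALSE	not in the study supplement panel
IL6ST	P40189	CNTF	FALSE	gp130 co-receptor of CNTFR
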