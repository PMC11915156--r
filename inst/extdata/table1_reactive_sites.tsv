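region	accession	gene	protein_name	position	localization
L	Q9DCS9	Ndufb10	NADH dehydrogenase 1 beta subcomplex subunit 10	77	Mitochondria, Cytosol
L	Q9CRB9	Chchd3	MICOS complex subunit Mic19	183	Nucleus, Mitochondria, Cytosol
L	P10126	Eef1a1	Elongation factor 1-alpha 1	411	Nucleus, Cytosol, Plasm membrane
L	A0A1S6GWI0	Ndufa8	NADH dehydrogenase 1 alpha subcomplex subunit 8	70	Mitochondria, Cytosol
L	P17563	Selenbp1	Selenium-binding protein 1	8	Nucleus, Cytosol
M	Q91X72	Hpx	Hemopexin	230	Extracellular space
M	P18572	Bsg	Basigin	203	Cytosol, Endoplasmic reticulum, Plasma membrane
M	P29699	Ahsg	Alpha-2-HS-glycoprotein (Fetuin-A)	219	Cytosol, Golgi apparatus, Extracellular space
M	Q9CVE7	Cmc1	COX assembly mitochondrial protein	57	Mitochondria, Cytosol
M	O70423	Aoc3	Membrane primary amine oxidase	430	Cytosol, Endoplasmic reticulum, Golgi apparatus, Plasma membrane, Extracellular space
M	Q8CGN5	Plin1	Perilipin-1	55	Cytosol, Endoplasmic reticulum
M	Q921I1	Tf	Serotransferrin	28	Extracellular space
M	Q921I1	Tf	Serotransferrin	67	Extracellular space
M	Q921I1	Tf	Serotransferrin	260	Extracellular space
M	Q921I1	Tf	Serotransferrin	363	Extracellular space
M	A0A1S6GWI4	Ndufs5	NADH dehydrogenase iron-sulfur protein 5	108	Mitochondria, Cytosol
M	Q546G4	Alb	Albumin	77	Cytosol, Endoplasmic reticulum, Golgi apparatus, Extracellular space
M	Q546G4	Alb	Albumin	86	Cytosol, Endoplasmic reticulum, Golgi apparatus, Extracellular space
M	Q546G4	Alb	Albumin	461	Cytosol, Endoplasmic reticulum, Golgi apparatus, Extracellular space
M	Q546G4	Alb	Albumin	462	Cytosol, Endoplasmic reticulum, Golgi apparatus, Extracellular space
M	Q546G4	Alb	Albumin	500	Cytosol, Endoplasmic reticulum, Golgi apparatus, Extracellular space
M	Q546G4	Alb	Albumin	501	Cytosol, Endoplasmic reticulum, Golgi apparatus, Extracellular space
M	Q546G4	Alb	Albumin	511	Cytosol, Endoplasmic reticulum, Golgi apparatus, Extracellular space
M	P10605	Ctsb	Cathepsin B	93	Mitochondria, Cytosol, Plasma membrane, Extracellular space
M	A0A1S6GWI0	Ndufa8	NADH dehydrogenase 1 alpha subcomplex subunit 8	144	Mitochondria, Cytosol
M	P56391	Cox6b1	Cytochrome c oxidase subunit 6B1	54	Mitochondria, Cytosol
N	Q8BMS1	Hadha	Trifunctional enzyme subunit alpha, mitochondrial	470	Mitochondria, Cytosol
N	Q7TPW6	Slc25a20	Mitochondrial carnitine/acylcarnitine translocase	155	Mitochondria, Cytosol
N	Q921I1	Tf	Serotransferrin	386	Extracellular space
N	Q921I1	Tf	Serotransferrin	395	Extracellular space
N	Q99KI0	Aco2	Aconitate hydratase, mitochondrial	126	Mitochondria, Cytosol
N	P51125	Cast	Calpastatin (Calpain inhibitor)	408	Cytosol, Endoplasmic reticulum
N	Q9D8N0	Eef1g	Elongation factor 1-gamma	266	Nucleus, Cytosol
N	Q8BH95	Echs1	Enoyl-CoA hydratase, mitochondrial	111	Mitochondria, Cytosol
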