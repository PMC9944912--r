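location	pop	size	region
Baltic Sea-North	BAS-N	25	Baltic Sea
Skagerak	SK	25	Atlantic
Norway Sea	NOR	19	Atlantic
North Sea-South	NS-S	24	Atlantic
Ireland-West	IR-W	25	Atlantic
Ireland-East	IR-E	25	Atlantic
English Channel	ECH	18	Atlantic
Biscay bay-France	BB-FR	23	Atlantic
Biscay bay-Southeast	BB-SE	25	Atlantic
Spain coast-West	SP-W	26	Atlantic
Adriatic Sea	AD	25	Mediterranean
Black Sea North	BLS-N	17	Black Sea
Black Sea South	BLS-S	28	Black Sea
Domestic	Farm 1	14	Domestic
Domestic	Farm 2	11	Domestic
Domestic	Farm 3	25	Domestic
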