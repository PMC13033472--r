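proband_id	sex	variant1	origin1	variant2	origin2	phase_method	group
3500	F	g.28017719_28020678delinsTTT		g.28017719_28020678delinsTTT		ccs_reads	two_PLP
1222	M	c.2228C>T		c.1327G>A		not_determined	two_PLP
1211	F	c.1901T>A	paternal	cxsv_143kb_184kb_del	maternal	trios	two_PLP
1180	F	g.28017719_28020678delinsTTT		g.28017719_28020678delinsTTT		not_determined	two_PLP
1148	M	c.1503+5G>A	paternal	c.163del	maternal	trios	two_PLP
1238	M	c.1327G>A	paternal	c.1116+5G>A	maternal	trios	two_PLP
1002	M	c.1503+5G>A		c.1327G>A		not_determined	two_PLP
1093	F	c.2310T>G		c.1465A>G		not_determined	two_PLP
1218	F	c.1025A>G	paternal	cxsv_143kb_184kb_del	maternal	trios	two_PLP
1232	M	cxsv_143kb_184kb_del	paternal	c.1327G>A	maternal	trios	two_PLP
1252	F	c.79G>A; c.1320G>C	paternal	c.79G>A; c.1320G>C	maternal	ccs_reads	two_PLP
1261	M	g.28017719_28020678delinsTTT		g.28017719_28020678delinsTTT		ccs_reads	two_PLP
1122	F	c.1327G>A		c.1327G>A		ccs_reads	two_PLP
1078	F	c.274del	paternal	c.1327G>A	maternal	trios	two_PLP
2035	F	g.27837375_28079574dup		c.1327G>A	maternal	maternal_only	two_PLP
2066	F	c.2207C>T		c.2201T>G		ccs_reads	two_PLP
2091	M	cxsv_143kb_invdup	paternal	c.1327G>A	maternal	trios	two_PLP
2105	F	c.1290T>A	paternal	c.1327G>A	maternal	ccs_reads	two_PLP
2112	M	c.1327G>A		g.28017719_28020678delinsTTT		not_determined	two_PLP
2163	F	g.28017719_28020678delinsTTT		g.28017719_28020678delinsTTT		ccs_reads	two_PLP
2180	M	c.1327G>A		c.2228C>T		not_determined	two_PLP
2189	F	c.79G>A; c.1320G>C	paternal	c.2330G>A	maternal	trios	two_PLP
2208	F	c.2228C>T		g.27965350_27973636delinsACACAACTTCATTGATAATGGCCTCTATTTA		not_determined	two_PLP
2280	M	c.1465A>G		c.1327G>A		not_determined	two_PLP
2282	M	c.1327G>A	paternal	c.2228C>T	maternal	trios	two_PLP
2379	F	c.1103C>T		c.1103C>T		ccs_reads	two_PLP
2415	F	c.1327G>A		c.2433-22889T>A		not_determined	two_PLP
2418	F	c.1465A>G		c.1465A>G		ccs_reads	two_PLP
2422	F	c.493C>T		g.27878517_28001141del		not_determined	two_PLP
2425	M	c.2228C>T		c.1327G>A		not_determined	two_PLP
2435	M	c.1327G>A	paternal	c.79G>A; c.1320G>C	maternal	ccs_reads	two_PLP
2451	M	c.1465A>G		c.1327G>A		not_determined	two_PLP
2456	F	c.1103C>T		g.28017719_28020678delinsTTT		not_determined	two_PLP
2457	M	c.1327G>A		cxsv_143kb_184kb_del		not_determined	two_PLP
2461	F	c.1465A>G	paternal	c.2037G>C	maternal	trios	two_PLP
2465	M	c.1255C>T		g.(23975851_24027348)_(28442183_28445507)del		ccs_reads	two_PLP
2552	M	c.1103C>T		c.1349C>T		not_determined	two_PLP
2557	F	c.1076G>A		c.1076G>A		ccs_reads	two_PLP
2587	F	c.1327G>A		c.1327G>A		ccs_reads	two_PLP
2593	M	c.1465A>G	paternal	c.1327G>A	maternal	trios	two_PLP
2612	M	g.28017719_28020678delinsTTT	paternal	c.1327G>A	maternal	trios	two_PLP
2622	F	c.1327G>A	paternal	g.28017719_28020678delinsTTT	maternal	not_determined	two_PLP
2637	F	c.1365-1G>C		c.163dup		trios	two_PLP
2669	F	c.928C>T		c.928C>T		ccs_reads	two_PLP
2682	M	c.79G>A; c.1320G>C		c.1327G>A		ccs_reads	two_PLP
2766	M	c.619_636del	paternal	c.1327G>A	maternal	trios	two_PLP
2781	M	c.1327G>A	paternal	cxsv_143kb_184kb_del	maternal	trios	two_PLP
2847	F	c.1327G>A	paternal	c.1465A>G	maternal	trios	two_PLP
2854	M	c.1349C>T		g.28017719_28020678delinsTTT		not_determined	two_PLP
2875	M	c.2228C>T	paternal	c.2020C>G	maternal	trios	two_PLP
2897	M	c.401G>A		c.401G>A		ccs_reads	two_PLP
2938	M	g.27878517_28001141del		g.27878517_28001141del		ccs_reads	two_PLP
2946	M	c.2228C>T	paternal	c.1327G>A	maternal	trios	two_PLP
2960	F	c.1182+1G>A		g.27844884_28020885del		ccs_reads	two_PLP
2976	M	c.1465A>G		c.1327G>A		not_determined	two_PLP
3005	F	c.1327G>A	paternal	c.2228C>T	maternal	trios	two_PLP
3029	F	g.28017719_28020678delinsTTT		c.1503+5G>A		not_determined	two_PLP
3030	F	c.1503+5G>A		g.28017719_28020678delinsTTT		not_determined	two_PLP
3032	M	c.2140-2A>G		g.28017719_28020678delinsTTT		not_determined	two_PLP
3034	F	c.1327G>A		c.612G>A		not_determined	two_PLP
3059	F	g.27844884_28020885del		g.[27975445_27984368dup;27984368_27984369insTTAACA]		ccs_reads	two_PLP
3111	F	cxsv_143kb_184kb_del	paternal	c.1327G>A	maternal	trios	two_PLP
3112	M	c.1045_1046del	paternal	c.1922C>T	maternal	trios	two_PLP
3117	F	c.228-2A>G		g.28017719_28020678delinsTTT		not_determined	two_PLP
3139	F	c.2244+2T>G	paternal	c.574-1G>A	maternal	trios	two_PLP
3146	F	g.28017719_28020678delinsTTT		g.27973488_28073270dup		ccs_reads	two_PLP
3188	F	c.79G>A; c.1320G>C		c.1327G>A		ccs_reads	two_PLP
3192	F	c.1327G>A	paternal	c.1465A>G	maternal	trios	two_PLP
3207	M	c.1327G>A		g.28017719_28020678delinsTTT		not_determined	two_PLP
3262	M	c.79G>A; c.1320G>C		cxsv_143kb_184kb_del		not_determined	two_PLP
3264	F	c.406C>T		c.1255C>T		not_determined	two_PLP
3273	F	c.1349C>T	paternal	c.1636G>A	maternal	trios	two_PLP
3285	M	c.2228C>T		c.2228C>T		ccs_reads	two_PLP
3289	M	g.27979571_27984604del		g.27979571_27984604del		ccs_reads	two_PLP
3290	F	g.27979571_27984604del		g.28017719_28020678delinsTTT		not_determined	two_PLP
3291	F	g.28017719_28020678delinsTTT		g.27979571_27984604del		not_determined	two_PLP
3293	F	g.28017719_28020678delinsTTT		g.28017719_28020678delinsTTT		ccs_reads	two_PLP
3294	F	g.28017719_28020678delinsTTT		c.2360C>T		not_determined	two_PLP
3295	M	g.28017719_28020678delinsTTT		g.28017719_28020678delinsTTT		ccs_reads	two_PLP
3296	M	g.27979571_27984604del		g.28017719_28020678delinsTTT		not_determined	two_PLP
3501	M	c.2324G>A		c.1239+5G>C		not_determined	one_PLP_one_VUS
1220	F	c.1897G>A		c.1255C>T	maternal	maternal_only	one_PLP_one_VUS
1225	M	c.1465A>G	paternal	c.1336A>G	maternal	trios	one_PLP_one_VUS
2055	M	c.1327G>A	paternal	c.632C>T	maternal	trios	one_PLP_one_VUS
2244	F	c.1095_1103del		c.1430T>C	maternal	not_determined	one_PLP_one_VUS
2546	M	c.1465A>G		c.2180T>C		not_determined	one_PLP_one_VUS
2556	M	c.2228C>T		c.1239+5G>C		not_determined	one_PLP_one_VUS
2666	F	g.28017719_28020678delinsTTT		c.632C>T		not_determined	one_PLP_one_VUS
2726	M	c.1951+1G>A		c.874T>C	maternal	trios	one_PLP_one_VUS
2784	M	g.28017719_28020678delinsTTT	paternal	c.1239+5G>C	maternal	trios	one_PLP_one_VUS
2837	F	c.819_822delinsGGTC	paternal	c.2359G>A	maternal	trios	one_PLP_one_VUS
2856	M	c.414C>A	paternal	c.1936A>G	maternal	trios	one_PLP_one_VUS
2912	M	c.700G>A	paternal	c.1465A>G	maternal	trios	one_PLP_one_VUS
2981	F	c.2370_2375delinsCGT		c.79G>A; c.1320G>C	maternal	maternal_only	one_PLP_one_VUS
3064	F	c.1555delG	paternal	c.632C>T	maternal	trios	one_PLP_one_VUS
3258	M	c.2201T>G		c.631C>G		not_determined	one_PLP_one_VUS
3288	F	g.27979571_27984604del		c.2170G>C		not_determined	one_PLP_one_VUS
3292	F	g.27979571_27984604del		c.2170G>C		not_determined	one_PLP_one_VUS
3502	M	c.1239+5G>C		c.1239+5G>C		ccs_reads	two_VUS
1209	M	c.1211C>T		c.2245-3_-2del	maternal	not_determined	two_VUS
1064	M	c.819_822delinsGGTC	paternal	c.2195C>T	maternal	trios	two_VUS
1275	F	c.1239+5G>C		c.1239+5G>C		ccs_reads	two_VUS
2431	F	c.757G>A	paternal	c.727C>T	maternal	ccs_reads	two_VUS
2720	F	c.819_822delinsGGTC	paternal	c.874T>C	maternal	ccs_reads	two_VUS
2795	F	c.819_822delinsGGTC		c.819_822delinsGGTC		ccs_reads	two_VUS
2820	F	c.874T>C		c.874T>C		ccs_reads	two_VUS
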