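plasma_cell	synthetic demo module (12 genes)	G00231	G00232	G00233	G00234	G00235	G00236	G00237	G00238	G00239	G00240	G00241	G00242
IGS	synthetic demo module (12 genes)	G00697	G00698	G00699	G00700	G00701	G00702	G00703	G00704	G00705	G00706	G00707	G00708
LDG	synthetic demo module (12 genes)	G00516	G00517	G00518	G00519	G00520	G00521	G00522	G00523	G00524	G00525	G00526	G00527
NK_cell	synthetic demo module (12 genes)	G00276	G00277	G00278	G00279	G00280	G00281	G00282	G00283	G00284	G00285	G00286	G00287
Treg	synthetic demo module (12 genes)	G00155	G00156	G00157	G00158	G00159	G00160	G00161	G00162	G00163	G00164	G00165	G00166
cell_cycle	synthetic demo module (12 genes)	G00683	G00684	G00685	G00686	G00687	G00688	G00689	G00690	G00691	G00692	G00693	G00694
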