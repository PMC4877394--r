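taxon	accession	class	size_bp	ir_length	gc_pct	n_genes	has_ir
Mesostigma_viride	NC_002186	Mesostigmatophyceae	118360	6057	30.1	137	1
Chlorokybus_atmophyticus	NC_008822	Chlorokybophyceae	152254	7640	38.2	138	1
Klebsormidium_sp_SAG_51_86	KU646497	Klebsormidiophyceae	130962	NA	40.6	112	NA
Klebsormidium_flaccidum	NC_024167	Klebsormidiophyceae	176832	51118	42.0	114	1
Entransia_fimbriata	KU646490	Klebsormidiophyceae	206025	60590	33.0	118	1
Chara_vulgaris	NC_008097	Charophyceae	184933	10919	26.2	127	1
Chaetosphaeridium_globosum	NC_004115	Coleochaetophyceae	131183	12431	29.6	125	1
Coleochaete_scutata	KU646493	Coleochaetophyceae	107236	NA	27.6	117	0
Mesotaenium_endlicherianum	NC_024169	Zygnematophyceae	142017	NA	42.2	124	0
Zygnema_circumcarinatum	NC_008117	Zygnematophyceae	165372	NA	31.1	125	0
Cylindrocystis_brebissonii	KU646495	Zygnematophyceae	136938	NA	29.8	122	0
Spirogyra_maxima	KU646489	Zygnematophyceae	129954	NA	30.1	124	0
Netrium_digitus	KU646491	Zygnematophyceae	131804	NA	31.4	125	0
Roya_anglica	NC_024168	Zygnematophyceae	138275	12568	33.1	122	1
Roya_obtusa	KU646496	Zygnematophyceae	138272	12568	33.1	122	1
Closterium_baillyanum	KU646494	Zygnematophyceae	201341	26784	39.3	124	1
Cosmarium_botrytis	KU646492	Zygnematophyceae	207850	24465	39.8	122	1
Staurastrum_punctulatum	NC_008116	Zygnematophyceae	157089	NA	32.5	122	0
Marchantia_polymorpha	NC_001319	Embryophyta	NA	NA	NA	NA	1
Physcomitrella_patens	NC_005087	Embryophyta	NA	NA	NA	NA	1
Syntrichia_ruralis	NC_012052	Embryophyta	NA	NA	NA	NA	1
Anthoceros_formosae	NC_004543	Embryophyta	NA	NA	NA	NA	1
Huperzia_lucidula	NC_006861	Embryophyta	NA	NA	NA	NA	1
Pinus_thunbergii	NC_001631	Embryophyta	NA	NA	NA	NA	1
Oryza_sativa	NC_001320	Embryophyta	NA	NA	NA	NA	1
Acorus_calamus	NC_007407	Embryophyta	NA	NA	NA	NA	1
Arabidopsis_thaliana	NC_000932	Embryophyta	NA	NA	NA	NA	1
Nicotiana_tabacum	NC_001879	Embryophyta	NA	NA	NA	NA	1
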