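((Mesostigma_viride,Chlorokybus_atmophyticus),(((Klebsormidium_flaccidum,Klebsormidium_sp_SAG_51_86),Entransia_fimbriata),(Chara_vulgaris,((Chaetosphaeridium_globosum,Coleochaete_scutata),((Mesotaenium_endlicherianum,((Zygnema_circumcarinatum,Cylindrocystis_brebissonii),(Spirogyra_maxima,(Netrium_digitus,((Roya_anglica,Roya_obtusa),(Closterium_baillyanum,(Cosmarium_botrytis,Staurastrum_punctulatum))))))),(((Marchantia_polymorpha,(Physcomitrella_patens,Syntrichia_ruralis)),Anthoceros_formosae),(Huperzia_lucidula,(Pinus_thunbergii,(Oryza_sativa,(Acorus_calamus,(Arabidopsis_thaliana,Nicotiana_tabacum)))))))))));
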