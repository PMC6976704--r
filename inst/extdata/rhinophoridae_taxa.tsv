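label	ingroup	source_note
Musca_spp	FALSE	
Amenia_sp	FALSE	
Bengalia_sp	FALSE	
Calliphora_vomitoria	FALSE	
Melinda_gentilis	FALSE	
Lucilia_sericata	FALSE	
Cuterebra_austeni	FALSE	
Pollenia_paupera	FALSE	
Eurychaeta_muscaria	FALSE	
Rhyncomya_impavida	FALSE	
Macquartia_tenebricosa	FALSE	
Acompomintho_lobata	TRUE	
Apomorphyto_inbio	TRUE	
Aporeomyia_sp	TRUE	
Axinia_disjuncta	TRUE	
Axinia_lucaris	TRUE	
Axinia_miranda	TRUE	
Azaisia_sp	TRUE	
Baniassa_fascipennis	TRUE	
Bezzimyia_barbarista	TRUE	
Bezzimyia_bisecta	TRUE	
Bezzimyia_busckii	TRUE	
Bezzimyia_hansoni	TRUE	
Bezzimyia_yepezi	TRUE	
Bixinia_collessi	TRUE	
Bixinia_winkleri	TRUE	printed matrix spelling: Bixinia winckleri
Comoromyia_sp1	TRUE	
Comoromyia_sp2	TRUE	
Kinabalumyia_pinax	TRUE	male characters from K. pinax (Sabah) concatenated with female characters of Kinabalumyia sp. 1 (Palawan); single OTU
Macrotarsina_longimana	TRUE	
Malayia_fuscinervis	TRUE	
Marshallicona_quitu	TRUE	printed matrix spelling: Marshallicona quitus
Maurhinophora_indoceanica	TRUE	
Melanomyiodes_capensis	TRUE	
Melanophora_asetosa	TRUE	
Melanophora_basilewskyi	TRUE	
Melanophora_chia	TRUE	
Melanophora_roralis	TRUE	
Metoplisa_carbonaria	TRUE	
Neotarsina_andina	TRUE	
Neotarsina_caraibica	TRUE	
Oplisa_tergestina	TRUE	
Parazamimus_congolensis	TRUE	
Paykullia_insularis	TRUE	
Paykullia_maculata	TRUE	
Phyto_adolescens	TRUE	
Phyto_angustifrons	TRUE	
Queximyia_flavipes	TRUE	
Rhinodonia_antiqua	TRUE	
Rhinodonia_flavicera	TRUE	
Rhinomorinia_sarcophagina	TRUE	
Rhinopeza_gracilis	TRUE	
Rhinophora_lepida	TRUE	
Shannoniella_cuspidata	TRUE	
Shannoniella_setinervis	TRUE	
Stevenia_deceptoria	TRUE	
Stevenia_palermitana	TRUE	
Tricogena_rubricosa	TRUE	
Tromodesia_angustifrons	TRUE	
Trypetidomima_fusca	TRUE	
Trypetidomima_lutea	TRUE	
Ventrops_aethiopicus	TRUE	
Ventrops_freidbergi	TRUE	
Ventrops_hannemariae	TRUE	
Ventrops_incisus	TRUE	
Ventrops_intermedius	TRUE	
Ventrops_milichioides	TRUE	
Ventrops_stuckenbergi	TRUE	
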