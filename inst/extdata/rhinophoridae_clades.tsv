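clade	taxa
A_Rhinophoridae	Acompomintho_lobata,Apomorphyto_inbio,Aporeomyia_sp,Axinia_disjuncta,Axinia_lucaris,Axinia_miranda,Azaisia_sp,Baniassa_fascipennis,Bezzimyia_barbarista,Bezzimyia_bisecta,Bezzimyia_busckii,Bezzimyia_hansoni,Bezzimyia_yepezi,Bixinia_collessi,Bixinia_winkleri,Comoromyia_sp1,Comoromyia_sp2,Kinabalumyia_pinax,Macrotarsina_longimana,Malayia_fuscinervis,Marshallicona_quitu,Maurhinophora_indoceanica,Melanomyiodes_capensis,Melanophora_asetosa,Melanophora_basilewskyi,Melanophora_chia,Melanophora_roralis,Metoplisa_carbonaria,Neotarsina_andina,Neotarsina_caraibica,Oplisa_tergestina,Parazamimus_congolensis,Paykullia_insularis,Paykullia_maculata,Phyto_adolescens,Phyto_angustifrons,Queximyia_flavipes,Rhinodonia_antiqua,Rhinodonia_flavicera,Rhinomorinia_sarcophagina,Rhinopeza_gracilis,Rhinophora_lepida,Shannoniella_cuspidata,Shannoniella_setinervis,Stevenia_deceptoria,Stevenia_palermitana,Tricogena_rubricosa,Tromodesia_angustifrons,Trypetidomima_fusca,Trypetidomima_lutea,Ventrops_aethiopicus,Ventrops_freidbergi,Ventrops_hannemariae,Ventrops_incisus,Ventrops_intermedius,Ventrops_milichioides,Ventrops_stuckenbergi
B_Phyto_group	Apomorphyto_inbio,Aporeomyia_sp,Axinia_disjuncta,Axinia_lucaris,Axinia_miranda,Comoromyia_sp1,Comoromyia_sp2,Kinabalumyia_pinax,Malayia_fuscinervis,Melanophora_asetosa,Melanophora_basilewskyi,Melanophora_chia,Melanophora_roralis,Parazamimus_congolensis,Paykullia_insularis,Paykullia_maculata,Phyto_adolescens,Phyto_angustifrons,Rhinodonia_antiqua,Rhinodonia_flavicera,Rhinopeza_gracilis
C_Australasian_Oriental	Aporeomyia_sp,Axinia_disjuncta,Axinia_lucaris,Axinia_miranda,Kinabalumyia_pinax,Rhinodonia_antiqua,Rhinodonia_flavicera,Rhinopeza_gracilis
D_Rhinodonia_Axinia	Axinia_disjuncta,Axinia_lucaris,Axinia_miranda,Rhinodonia_antiqua,Rhinodonia_flavicera
E_Stevenia_group	Acompomintho_lobata,Azaisia_sp,Baniassa_fascipennis,Macrotarsina_longimana,Maurhinophora_indoceanica,Melanomyiodes_capensis,Metoplisa_carbonaria,Oplisa_tergestina,Queximyia_flavipes,Rhinomorinia_sarcophagina,Rhinophora_lepida,Stevenia_deceptoria,Stevenia_palermitana,Tricogena_rubricosa,Tromodesia_angustifrons,Ventrops_aethiopicus,Ventrops_freidbergi,Ventrops_hannemariae,Ventrops_incisus,Ventrops_intermedius,Ventrops_milichioides,Ventrops_stuckenbergi,Bezzimyia_barbarista,Bezzimyia_bisecta,Bezzimyia_busckii,Bezzimyia_hansoni,Bezzimyia_yepezi,Bixinia_collessi,Bixinia_winkleri,Marshallicona_quitu,Neotarsina_andina,Neotarsina_caraibica,Shannoniella_cuspidata,Shannoniella_setinervis,Trypetidomima_fusca,Trypetidomima_lutea
F_Old_World_flat_larva	Acompomintho_lobata,Azaisia_sp,Baniassa_fascipennis,Macrotarsina_longimana,Maurhinophora_indoceanica,Melanomyiodes_capensis,Metoplisa_carbonaria,Oplisa_tergestina,Queximyia_flavipes,Rhinomorinia_sarcophagina,Rhinophora_lepida,Stevenia_deceptoria,Stevenia_palermitana,Tricogena_rubricosa,Tromodesia_angustifrons
H_Ventrops	Ventrops_aethiopicus,Ventrops_freidbergi,Ventrops_hannemariae,Ventrops_incisus,Ventrops_intermedius,Ventrops_milichioides,Ventrops_stuckenbergi
I_mostly_Neotropical	Bezzimyia_barbarista,Bezzimyia_bisecta,Bezzimyia_busckii,Bezzimyia_hansoni,Bezzimyia_yepezi,Bixinia_collessi,Bixinia_winkleri,Marshallicona_quitu,Neotarsina_andina,Neotarsina_caraibica,Shannoniella_cuspidata,Shannoniella_setinervis,Trypetidomima_fusca,Trypetidomima_lutea
Kinabalumyia	Kinabalumyia_pinax
Neotarsina	Neotarsina_andina,Neotarsina_caraibica
Marshallicona	Marshallicona_quitu
Maurhinophora	Maurhinophora_indoceanica
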