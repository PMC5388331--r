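((Cladrastis_wilsonii,Styphnolobium_japonicum),(Camoensia_brevicalyx,((Crotalaria_capensis,Lupinus_luteus),((Anagyris_foetida,(Baptisia_australis,(Piptanthus_nepalensis,Thermopsis_fabacea))),(Maackia_fauriei,(Salweenia_bouffordiana,((Bolusanthus_speciosus,Dicraeopetalum_mahafaliense),((Sophora_koreensis,Sophora_flavescens),Euchresta_japonica))))))));
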