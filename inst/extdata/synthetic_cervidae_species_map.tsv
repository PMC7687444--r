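Cervus_nippon_01	Cervus_nippon
Cervus_nippon_02	Cervus_nippon
Cervus_nippon_03	Cervus_nippon
Cervus_elaphus_01	Cervus_elaphus
Cervus_elaphus_02	Cervus_elaphus
Cervus_elaphus_03	Cervus_elaphus
Axis_porcinus_01	Axis_porcinus
Axis_porcinus_02	Axis_porcinus
Axis_porcinus_03	Axis_porcinus
Dama_dama_01	Dama_dama
Dama_dama_02	Dama_dama
Dama_dama_03	Dama_dama
Elaphurus_davidianus_01	Elaphurus_davidianus
Elaphurus_davidianus_02	Elaphurus_davidianus
Elaphurus_davidianus_03	Elaphurus_davidianus
Elaphodus_cephalophus_01	Elaphodus_cephalophus
Elaphodus_cephalophus_02	Elaphodus_cephalophus
Rusa_unicolor_01	Rusa_unicolor
Rusa_unicolor_02	Rusa_unicolor
Rangifer_tarandus_01	Rangifer_tarandus
Rangifer_tarandus_02	Rangifer_tarandus
Rangifer_tarandus_03	Rangifer_tarandus
Rangifer_tarandus_04	Rangifer_tarandus
Rangifer_tarandus_05	Rangifer_tarandus
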