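(H_armigera:0.25,(((M_gaschkewitschii:0.06,A_ochracea:0.06):0.03,M_sexta:0.08):0.02,((C_hylas:0.05,H_affinis:0.05):0.04,(A_rubiginosa:0.07,(D_nerii:0.06,(N_himachala:0.07,(T_japonica:0.06,(M_pyrrhosticta:0.04,(M_bombylans:0.03,M_stellatarum:0.03):0.02):0.03):0.02):0.02):0.02):0.02):0.03):0.05);
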