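# Activity labels and diurnal clade tags for the hawkmoth species-tree
# fixture. D1-D3 are the three independent diurnal emergences.
activity:
  H_armigera: nocturnal
  M_gaschkewitschii: nocturnal
  A_ochracea: nocturnal
  M_sexta: nocturnal
  A_rubiginosa: nocturnal
  D_nerii: nocturnal
  T_japonica: nocturnal
  C_hylas: diurnal
  H_affinis: diurnal
  N_himachala: diurnal
  M_pyrrhosticta: diurnal
  M_bombylans: diurnal
  M_stellatarum: diurnal
clades:
  D1: [C_hylas, H_affinis]
  D2: [N_himachala]
  D3: [M_pyrrhosticta, M_bombylans, M_stellatarum]
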