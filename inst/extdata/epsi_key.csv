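item,subscale
epsi_1,synthesis
epsi_2,synthesis
epsi_3,synthesis
epsi_4,synthesis
epsi_5,synthesis
epsi_6,synthesis
epsi_7,confusion
epsi_8,confusion
epsi_9,confusion
epsi_10,confusion
epsi_11,confusion
epsi_12,confusion
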