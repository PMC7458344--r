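sample	class
HI_01	HI
HI_02	HI
HI_03	HI
HI_04	HI
HI_05	HI
HI_06	HI
HI_07	HI
HI_08	HI
HI_09	HI
HI_10	HI
HI_11	HI
HI_12	HI
HI_13	HI
HI_14	HI
HI_15	HI
LOW_01	LOW
LOW_02	LOW
LOW_03	LOW
LOW_04	LOW
LOW_05	LOW
LOW_06	LOW
LOW_07	LOW
LOW_08	LOW
LOW_09	LOW
LOW_10	LOW
LOW_11	LOW
LOW_12	LOW
LOW_13	LOW
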