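stromal_synthetic	synthetic stand-in stromal signature (not the published gene list)	STROMAL_M01	STROMAL_M02	STROMAL_M03	STROMAL_M04	STROMAL_M05	STROMAL_M06	STROMAL_M07	STROMAL_M08	STROMAL_M09	STROMAL_M10	STROMAL_M11	STROMAL_M12	STROMAL_M13	STROMAL_M14	STROMAL_M15
immune_synthetic	synthetic stand-in immune signature (not the published gene list)	IMMUNE_M01	IMMUNE_M02	IMMUNE_M03	IMMUNE_M04	IMMUNE_M05	IMMUNE_M06	IMMUNE_M07	IMMUNE_M08	IMMUNE_M09	IMMUNE_M10	IMMUNE_M11	IMMUNE_M12	IMMUNE_M13	IMMUNE_M14	IMMUNE_M15
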