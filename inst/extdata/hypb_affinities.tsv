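metal	kd_molar	enabled
Mn2+	NA	FALSE
Fe2+	NA	FALSE
Co2+	NA	FALSE
Ni2+	6e-14	TRUE
Zn2+	2.2e-11	TRUE
Cu1+	NA	FALSE
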