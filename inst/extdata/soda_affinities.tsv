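metal	kd_molar	enabled
Mn2+	3.1e-9	TRUE
Fe2+	2.5e-8	TRUE
Co2+	NA	FALSE
Ni2+	NA	FALSE
Zn2+	NA	FALSE
Cu1+	NA	FALSE
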