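# Buffered available metal concentrations in E. coli JM109 (DE3) cultured in
# LB media, per growth condition. Values as printed in the published
# availability table (rounded; SDs over biological replicates in `sd`,
# absent for boundary-defining conditions). The Zn2+ `concentration` is the
# two-sensor midpoint; the Zur-only and ZntR-only values are carried in
# zinc_zur / zinc_zntr.
provenance: >-
  qPCR-calibrated metal-sensor readouts for E. coli JM109 (DE3) in LB media
  (aerobic, anaerobic 2 h, and H2O2-treated cultures).
presets:
  aerobic:
    metals:
      - {metal: Mn2+, concentration: 7.0e-6, sd: 4.0e-6}
      - {metal: Fe2+, concentration: 1.9e-6, sd: 0.2e-6}
      - {metal: Co2+, concentration: 7.0e-11, sd: 1.0e-11}
      - metal: Zn2+
        concentration: 2.0e-12
        zinc_zur: {concentration: 7.0e-12, sd: 1.0e-12}
        zinc_zntr: {concentration: 4.0e-13, sd: 1.0e-13}
      - {metal: Ni2+, concentration: 1.3e-13, sd: 0.7e-13}
      - {metal: Cu1+, concentration: 4.5e-20, sd: 0.6e-20}
  anaerobic:
    metals:
      - {metal: Mn2+, concentration: 1.0e-5, sd: 0.3e-5}
      - {metal: Fe2+, concentration: 7.0e-7, sd: 2.0e-7}
      - {metal: Co2+, concentration: 7.1e-11, sd: 0.5e-11}
      - metal: Zn2+
        concentration: 1.4e-12
        zinc_zur: {concentration: 6.7e-12, sd: 0.9e-12}
        zinc_zntr: {concentration: 2.9e-13, sd: 0.3e-13}
      - {metal: Ni2+, concentration: 9.0e-14, sd: 2.0e-14}
      - {metal: Cu1+, concentration: 1.5e-19, sd: 0.2e-19}
  h2o2:
    metals:
      - {metal: Mn2+, concentration: 9.0e-5, sd: 2.0e-5}
      - {metal: Fe2+, concentration: 3.4e-6}          # boundary condition
      - {metal: Co2+, concentration: 2.4e-11}         # boundary condition
      - metal: Zn2+
        concentration: 2.2e-12
        zinc_zur: {concentration: 3.2e-11}            # boundary condition
        zinc_zntr: {concentration: 1.6e-13, sd: 0.4e-13}
      - {metal: Ni2+, concentration: 5.0e-13, sd: 2.0e-13}
      - {metal: Cu1+, concentration: 1.1e-20}         # boundary condition
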