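# SYNTHETIC sensor thermodynamic constants -- placeholder values, not
# measurements. The true constants for the Salmonella-characterized sensors
# live in the primary literature and its supplementary spreadsheets and are
# not redistributed here. These records exist so that the calibration
# pipeline, response curves, and synthetic-data round trips can run end to
# end: each sensor's 0.01-0.99 dynamic range was chosen to bracket the
# packaged availability presets for its metal. Replace every record with
# measured constants before interpreting real Cq data.
sensors:
  - name: MntR
    metal: Mn2+
    class: co-repressor
    k_metal: 3.8e-3
    k_dna_apo: 1.0e-6
    k_dna_holo: 1.0e-9
    abundance_low: 100
    abundance_high: 1000
    n_targets: 1
    cell_volume: 1.0e-15
    provenance: synthetic placeholder
  - name: Fur
    metal: Fe2+
    class: co-repressor
    k_metal: 3.3e-4
    k_dna_apo: 1.0e-6
    k_dna_holo: 1.0e-9
    abundance_low: 100
    abundance_high: 1000
    n_targets: 1
    cell_volume: 1.0e-15
    provenance: synthetic placeholder
  - name: RcnR
    metal: Co2+
    class: de-repressor
    k_metal: 8.4e-14
    k_dna_apo: 1.0e-9
    k_dna_holo: 1.0e-6
    abundance_low: 100
    abundance_high: 1000
    n_targets: 1
    cell_volume: 1.0e-15
    provenance: synthetic placeholder
  - name: NikR
    metal: Ni2+
    class: co-repressor
    k_metal: 1.7e-11
    k_dna_apo: 1.0e-6
    k_dna_holo: 1.0e-9
    abundance_low: 100
    abundance_high: 1000
    n_targets: 1
    cell_volume: 1.0e-15
    provenance: synthetic placeholder
  - name: Zur
    metal: Zn2+
    class: co-repressor
    k_metal: 2.3e-9
    k_dna_apo: 1.0e-6
    k_dna_holo: 1.0e-9
    abundance_low: 100
    abundance_high: 1000
    n_targets: 1
    cell_volume: 1.0e-15
    provenance: synthetic placeholder
  - name: ZntR
    metal: Zn2+
    class: activator
    k_metal: 3.1e-11
    k_dna_apo: 1.0e-6
    k_dna_holo: 1.0e-9
    abundance_low: 50
    abundance_high: 500
    n_targets: 1
    cell_volume: 1.0e-15
    provenance: synthetic placeholder
  - name: CueR
    metal: Cu1+
    class: activator
    k_metal: 5.0e-18
    k_dna_apo: 1.0e-6
    k_dna_holo: 1.0e-9
    abundance_low: 50
    abundance_high: 500
    n_targets: 1
    cell_volume: 1.0e-15
    provenance: synthetic placeholder
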