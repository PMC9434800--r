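# Shared in-code fixtures.

demo_sensor <- function(class = "co-repressor", k_metal = 1e-12,
                        abundance_low = 100, abundance_high = 1000, ...) {
  if (class == "de-repressor") {
    metalation::sensor_params("demo", "Co2+", class, k_metal,
                              k_dna_apo = 1e-9, k_dna_holo = 1e-6,
                              abundance_low = abundance_low,
                              abundance_high = abundance_high,
                              n_targets = 1, ...)
  } else {
    metalation::sensor_params("demo", "Ni2+", class, k_metal,
                              k_dna_apo = 1e-6, k_dna_holo = 1e-9,
                              abundance_low = abundance_low,
                              abundance_high = abundance_high,
                              n_targets = 1, ...)
  }
}

packaged_sensors <- function() {
  metalation::read_sensor_params(
    system.file("extdata", "sensors_synthetic.yaml", package = "metalation"))
}

# Cq table with a hand-computable delta-delta-Cq structure:
#   baseline: gene 25.0/25.3/24.7 vs rpoD mean 18.0 -> mean dCq 7.0
#   induced : gene 22.0/22.2/21.8 vs rpoD mean 18.1 -> mean dCq 3.9
#   ddCq = -3.1, fold change = 2^3.1
hand_cq_table <- function() {
  data.frame(
    gene = rep(c("mntS", "rpoD"), each = 6),
    condition = rep(rep(c("baseline", "induced"), each = 3), 2),
    replicate = rep(1:3, 4),
    cq = c(25.0, 25.3, 24.7, 22.0, 22.2, 21.8,
           18.0, 18.1, 17.9, 18.2, 18.0, 18.1),
    ntc_cq = NA_real_, mrt_cq = NA_real_,
    stringsAsFactors = FALSE
  )
}
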