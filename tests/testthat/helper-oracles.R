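# Independent numerical oracles. These deliberately avoid the package's
# closed-form quadratic reduction: the equilibrium oracle treats free apo
# sensor P and free operator D as unknowns and solves the two mass balances
# by nested bisection on the raw equilibrium expressions.

N_AVOGADRO <- 6.02214076e23

# Solve the five-species system by bisection on P (outer) with, for each P,
# bisection on D against the operator mass balance (inner).
oracle_equilibrium <- function(params, free_metal, n_sensor) {
  M <- free_metal
  Ptot <- n_sensor / (N_AVOGADRO * params$cell_volume)
  Dtot <- params$n_targets / (N_AVOGADRO * params$cell_volume)

  species <- function(P, D) {
    PM <- P * M / params$k_metal
    PD <- P * D / params$k_dna_apo
    PMD <- PM * D / params$k_dna_holo
    list(P = P, PM = PM, D = D, PD = PD, PMD = PMD)
  }
  solve_D <- function(P) {
    lo <- 0; hi <- Dtot
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      s <- species(P, mid)
      if (s$D + s$PD + s$PMD > Dtot) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  sensor_excess <- function(P) {
    s <- species(P, solve_D(P))
    s$P + s$PM + s$PD + s$PMD - Ptot
  }
  lo <- 0; hi <- Ptot
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (sensor_excess(mid) > 0) hi <- mid else lo <- mid
  }
  P <- (lo + hi) / 2
  out <- species(P, solve_D(P))
  out$P_total <- Ptot
  out$D_total <- Dtot
  out
}

# Dense-grid inversion: locate theta_target on a fine log grid of the
# forward response, refine by plain bisection on the bracketing interval.
oracle_invert <- function(params, theta_target, bracket = c(1e-25, 1e-1),
                          n_grid = 400L, ...) {
  lg <- seq(log10(bracket[1]), log10(bracket[2]), length.out = n_grid)
  th <- metalation::sensor_occupancy(params, 10^lg, ...)
  diffs <- th - theta_target
  idx <- which(diffs[-1] * diffs[-length(diffs)] <= 0)[1]
  if (is.na(idx)) stop("oracle_invert: target not bracketed")
  lo <- lg[idx]; hi <- lg[idx + 1]
  rising <- th[idx + 1] > th[idx]
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    val <- metalation::sensor_occupancy(params, 10^mid, ...)
    if ((val > theta_target) == rising) hi <- mid else lo <- mid
  }
  10^((lo + hi) / 2)
}

# Partition-function enumeration for single-site competitive binding:
# states = {empty site} U {site bound by metal i}, Boltzmann weight of the
# bound state proportional to [M_i]/K_D,i.
oracle_occupancy <- function(conc, kd) {
  weights <- c(1, conc / kd)          # state 1 = empty
  probs <- weights / sum(weights)
  probs[-1]
}

random_sensor <- function() {
  class <- sample(c("co-repressor", "de-repressor", "activator"), 1)
  km <- 10^stats::runif(1, -14, -6)
  kd1 <- 10^stats::runif(1, -10, -6)
  kd2 <- kd1 * 10^stats::runif(1, 1, 4)
  if (class == "de-repressor") {
    kapo <- kd1; kholo <- kd2
  } else {
    kapo <- kd2; kholo <- kd1
  }
  low <- stats::runif(1, 20, 500)
  metalation::sensor_params(
    name = "rand", metal = sample(metalation::metal_ions(), 1), class = class,
    k_metal = km, k_dna_apo = kapo, k_dna_holo = kholo,
    abundance_low = low, abundance_high = low * stats::runif(1, 1, 10),
    n_targets = sample(1:5, 1), cell_volume = 1e-15)
}
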