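#' Describe a synthetic qPCR experiment with known ground truth
#'
#' A scenario fixes, per condition, the true buffered metal concentrations,
#' and the nuisance structure of the measurement: Gaussian Cq noise,
#' replicate count, per-gene baseline Cq levels, and an optional
#' reference-gene drift injected into chosen conditions (to exercise the
#' quality-control rules). The first condition in `conditions` is the
#' minimum-expression baseline and the last is the maximum-expression
#' boundary used to anchor the dynamic range.
#'
#' @param truth data.frame with columns `condition` and one column per metal
#'   symbol giving the true buffered concentration (M), or a named list of
#'   per-condition named concentration vectors.
#' @param noise_sd Gaussian Cq noise standard deviation (cycles), `>= 0`.
#' @param n_replicates biological replicates per condition, `>= 1`.
#' @param baseline_cq named numeric vector of baseline-condition Cq per gene;
#'   genes not named default to 25 (reference genes to 18).
#' @param reference_drift named numeric vector: Cq shift added to the
#'   reference gene in the named condition(s).
#' @param fold_change_max named numeric vector of true maximum fold changes
#'   per gene (default 50 for every gene): the expression span between the
#'   two boundary conditions.
#' @return A `"synthetic_scenario"` list.
#' @export
synthetic_scenario <- function(truth, noise_sd = 0, n_replicates = 3,
                               baseline_cq = NULL, reference_drift = NULL,
                               fold_change_max = NULL) {
  if (is.list(truth) && !is.data.frame(truth)) {
    conds <- names(truth)
    metals <- unique(unlist(lapply(truth, names)))
    assert_metal(metals)
    truth <- do.call(rbind, lapply(conds, function(cn) {
      row <- as.data.frame(as.list(truth[[cn]]), check.names = FALSE)
      row <- cbind(data.frame(condition = cn, stringsAsFactors = FALSE), row)
      row
    }))
  }
  stopifnot(is.data.frame(truth), "condition" %in% names(truth),
            noise_sd >= 0, n_replicates >= 1)
  structure(list(truth = truth, noise_sd = noise_sd,
                 n_replicates = as.integer(n_replicates),
                 baseline_cq = baseline_cq, reference_drift = reference_drift,
                 fold_change_max = fold_change_max),
            class = "synthetic_scenario")
}

theta_to_fold_change <- function(theta, fold_change_max, class) {
  frac <- if (class == "activator") (theta - 0.01) / 0.98
          else (0.99 - theta) / 0.98
  1 + frac * (fold_change_max - 1)
}

#' Generate a synthetic Cq table from ground-truth availabilities
#'
#' Forward-simulates the entire calibration pipeline in reverse: true
#' concentration -> sensor occupancy (equilibrium model) -> fold change
#' (inverse of the linear theta calibration) -> delta-delta-Cq -> replicate
#' Cq values with Gaussian noise. The first condition of the scenario is the
#' minimum-expression baseline; an extra boundary condition named
#' `"__max__<gene>"` is not generated -- instead the scenario's last
#' condition is forced to the maximum fold change so the dynamic range is
#' anchored within the table. Deterministic under a fixed seed.
#'
#' @param scenario a [synthetic_scenario()].
#' @param sensors named list of [sensor_params()] (as from
#'   [read_sensor_params()]), keyed by sensor name.
#' @param seed integer seed.
#' @param genes which regulated genes to simulate; defaults to every gene in
#'   [sensor_gene_map()] whose sensor is present in `sensors`.
#' @param reference_gene reference gene name (default `"rpoD"`).
#' @return List with `records` (a Cq data.frame as read by
#'   [read_cq_table()]), `truth` (the scenario truth table), and `boundaries`
#'   (data.frame `gene`, `min_condition`, `max_condition`,
#'   `fold_change_max`).
#' @export
generate_synthetic_qpcr <- function(scenario, sensors, seed,
                                    genes = NULL, reference_gene = "rpoD") {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(seed)
  map <- sensor_gene_map()
  map <- map[map$sensor %in% names(sensors), , drop = FALSE]
  if (!is.null(genes)) map <- map[map$gene %in% genes, , drop = FALSE]
  if (!nrow(map)) stop("no genes to simulate", call. = FALSE)

  conds <- scenario$truth$condition
  baseline <- conds[1]
  maxcond <- conds[length(conds)]
  nrep <- scenario$n_replicates

  cq_of <- function(gene) {
    if (!is.null(scenario$baseline_cq) &&
        gene %in% names(scenario$baseline_cq)) {
      return(scenario$baseline_cq[[gene]])
    }
    if (gene %in% reference_genes()) 18 else 25
  }
  fcmax_of <- function(gene) {
    if (!is.null(scenario$fold_change_max) &&
        gene %in% names(scenario$fold_change_max)) {
      return(scenario$fold_change_max[[gene]])
    }
    50
  }

  rows <- list()
  boundaries <- list()
  for (k in seq_len(nrow(map))) {
    gene <- map$gene[k]
    sensor <- sensors[[map$sensor[k]]]
    fcmax <- fcmax_of(gene)
    for (cond in conds) {
      if (!sensor$metal %in% names(scenario$truth)) {
        stop("scenario lacks a ", sensor$metal, " truth column",
             call. = FALSE)
      }
      truth_c <- scenario$truth[scenario$truth$condition == cond,
                                sensor$metal]
      if (!length(truth_c) || is.na(truth_c)) {
        stop("scenario lacks a ", sensor$metal, " truth for condition '",
             cond, "'", call. = FALSE)
      }
      theta <- sensor_occupancy(sensor, as.numeric(truth_c))
      anchor_hi <- if (sensor$class == "activator") 0.99 else 0.01
      anchor_lo <- if (sensor$class == "activator") 0.01 else 0.99
      if (cond == baseline) theta <- anchor_lo
      if (cond == maxcond) theta <- anchor_hi
      if (theta < 0.01 - 1e-9 || theta > 0.99 + 1e-9) {
        stop("truth for ", sensor$name, " in condition '", cond,
             "' falls outside the sensor's calibrated range (theta = ",
             signif(theta, 4), ")", call. = FALSE)
      }
      fc <- theta_to_fold_change(min(max(theta, 0.01), 0.99), fcmax,
                                 sensor$class)
      ddcq <- -log2(fc)
      for (rep_i in seq_len(nrep)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, condition = cond, replicate = rep_i,
          cq = cq_of(gene) + ddcq + stats::rnorm(1, 0, scenario$noise_sd),
          ntc_cq = NA_real_, mrt_cq = NA_real_, stringsAsFactors = FALSE)
      }
    }
    boundaries[[length(boundaries) + 1L]] <- data.frame(
      gene = gene, min_condition = baseline, max_condition = maxcond,
      fold_change_max = fcmax, stringsAsFactors = FALSE)
  }

  # reference gene rows (per condition, with optional injected drift)
  for (cond in conds) {
    drift <- 0
    if (!is.null(scenario$reference_drift) &&
        cond %in% names(scenario$reference_drift)) {
      drift <- scenario$reference_drift[[cond]]
    }
    for (rep_i in seq_len(nrep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = reference_gene, condition = cond, replicate = rep_i,
        cq = cq_of(reference_gene) + drift +
          stats::rnorm(1, 0, scenario$noise_sd),
        ntc_cq = NA_real_, mrt_cq = NA_real_, stringsAsFactors = FALSE)
    }
  }

  list(records = do.call(rbind, rows),
       truth = scenario$truth,
       boundaries = do.call(rbind, boundaries))
}

#' Recover availabilities from a (synthetic or real) Cq table
#'
#' QC-filters the records, then runs [calibrate_sensor()] for every gene
#' with a declared boundary pair, producing an availability table with one
#' row per sensor and condition.
#'
#' @param records Cq records (as from [read_cq_table()] or
#'   [generate_synthetic_qpcr()]).
#' @param sensors named list of [sensor_params()].
#' @param boundaries data.frame with columns `gene`, `min_condition`,
#'   `max_condition` (as emitted by [generate_synthetic_qpcr()]).
#' @param conditions conditions to estimate; default: all non-boundary
#'   conditions present.
#' @param reference_gene,second_reference passed to [qc_filter()].
#' @param constants a [thermo_constants()] object.
#' @return List with `estimates` (data.frame: `metal`, `sensor`,
#'   `condition`, `concentration`, `sd`, `delta_g`, `n`) and `exclusions`
#'   (the QC report).
#' @export
calibrate_cq_table <- function(records, sensors, boundaries,
                               conditions = NULL, reference_gene = "rpoD",
                               second_reference = NULL,
                               constants = thermo_constants()) {
  map <- sensor_gene_map()
  qc <- qc_filter(records,
                  control_condition = boundaries$min_condition[1],
                  reference_gene = reference_gene,
                  second_reference = second_reference)
  est <- list()
  for (k in seq_len(nrow(boundaries))) {
    gene <- boundaries$gene[k]
    sensor <- sensors[[map$sensor[match(gene, map$gene)]]]
    if (is.null(sensor)) next
    conds <- conditions %||%
      setdiff(unique(qc$records$condition[qc$records$gene == gene]),
              c(boundaries$min_condition[k], boundaries$max_condition[k]))
    for (cond in conds) {
      e <- calibrate_sensor(qc$records, sensor, gene, cond,
                            boundaries$min_condition[k],
                            boundaries$max_condition[k],
                            reference_gene = reference_gene,
                            constants = constants)
      est[[length(est) + 1L]] <- data.frame(
        metal = e$metal, sensor = e$sensor, condition = e$condition,
        concentration = e$concentration, sd = e$sd, delta_g = e$delta_g,
        n = e$n, stringsAsFactors = FALSE)
    }
  }
  list(estimates = if (length(est)) do.call(rbind, est) else NULL,
       exclusions = qc$exclusions)
}
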