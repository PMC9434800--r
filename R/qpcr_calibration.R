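#' Read a qPCR quantification-cycle (Cq) table
#'
#' Expects CSV or TSV (sniffed from the extension) with columns `gene`,
#' `condition`, `replicate`, `cq`, and optionally `ntc_cq` (no-template
#' control) and `mrt_cq` (minus-reverse-transcriptase control). Cq values are
#' assumed to be amplicon-efficiency-corrected upstream; quantification is
#' strictly base-2.
#'
#' @param path path to the table.
#' @return data.frame with the columns above (`ntc_cq`/`mrt_cq` filled with
#'   `NA` when absent).
#' @export
read_cq_table <- function(path) {
  if (!file.exists(path)) stop("Cq table not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  needed <- c("gene", "condition", "replicate", "cq")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("Cq table ", path, " missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("ntc_cq", "mrt_cq")) if (is.null(df[[col]])) df[[col]] <- NA_real_
  if (any(!is.finite(df$cq)) || any(df$cq <= 0)) {
    stop("Cq values must be finite and positive", call. = FALSE)
  }
  df
}

#' Quality-control filter for Cq records
#'
#' Applies the two sample-rejection rules used before any quantification:
#'
#' * **Reference shift** -- a whole condition is excluded when the mean
#'   reference-gene Cq differs from the control condition's mean by more
#'   than 2 cycles, unless a second reference gene passes the same test
#'   (the condition is then retained and the rescue is recorded).
#' * **Contamination controls** -- an individual sample is rejected when its
#'   no-template-control or minus-RT-control Cq, rounded to the nearest
#'   integer difference, is fewer than 10 cycles above the sample Cq.
#'
#' Conditions lacking reference-gene records are excluded outright.
#'
#' @param records data.frame as from [read_cq_table()].
#' @param control_condition label of the control (comparison) condition.
#' @param reference_gene primary reference gene (default `"rpoD"`).
#' @param second_reference optional rescue reference gene (e.g. `"gyrA"`).
#' @param ref_shift_threshold cycles; default 2.
#' @param control_margin cycles; default 10.
#' @return List with `records` (retained rows) and `exclusions`, a
#'   data.frame of machine-readable exclusions with columns `scope`
#'   (`"condition"` or `"sample"`), `condition`, `gene`, `replicate`,
#'   `rule` (`"ref-shift"`, `"no-reference"`, `"ntc"`, `"mrt"`) and `detail`.
#' @export
qc_filter <- function(records, control_condition, reference_gene = "rpoD",
                      second_reference = NULL, ref_shift_threshold = 2,
                      control_margin = 10) {
  stopifnot(is.data.frame(records))
  excl <- list()
  note <- function(scope, condition, gene, replicate, rule, detail) {
    data.frame(scope = scope, condition = condition, gene = gene,
               replicate = as.character(replicate), rule = rule,
               detail = detail, stringsAsFactors = FALSE)
  }

  ref_mean <- function(cond, gene) {
    x <- records$cq[records$condition == cond & records$gene == gene]
    if (!length(x)) NA_real_ else mean(x)
  }
  ctrl_mean <- ref_mean(control_condition, reference_gene)
  if (is.na(ctrl_mean)) {
    stop("no ", reference_gene, " records for control condition '",
         control_condition, "'", call. = FALSE)
  }

  keep_condition <- character()
  for (cond in unique(records$condition)) {
    m <- ref_mean(cond, reference_gene)
    if (is.na(m)) {
      excl[[length(excl) + 1L]] <- note(
        "condition", cond, reference_gene, NA, "no-reference",
        paste0("no ", reference_gene, " records"))
      next
    }
    shift <- abs(m - ctrl_mean)
    if (shift > ref_shift_threshold) {
      rescued <- FALSE
      if (!is.null(second_reference)) {
        m2 <- ref_mean(cond, second_reference)
        m2c <- ref_mean(control_condition, second_reference)
        if (!is.na(m2) && !is.na(m2c) &&
            abs(m2 - m2c) <= ref_shift_threshold) {
          rescued <- TRUE
        }
      }
      if (!rescued) {
        excl[[length(excl) + 1L]] <- note(
          "condition", cond, reference_gene, NA, "ref-shift",
          sprintf("mean %s Cq shift %.2f > %g vs '%s'", reference_gene,
                  shift, ref_shift_threshold, control_condition))
        next
      }
    }
    keep_condition <- c(keep_condition, cond)
  }

  kept <- records[records$condition %in% keep_condition, , drop = FALSE]

  drop_row <- logical(nrow(kept))
  for (i in seq_len(nrow(kept))) {
    for (ctl in c(ntc = "ntc_cq", mrt = "mrt_cq")) {
      v <- kept[[ctl]][i]
      if (!is.na(v) && round(v - kept$cq[i]) < control_margin) {
        rule <- if (ctl == "ntc_cq") "ntc" else "mrt"
        excl[[length(excl) + 1L]] <- note(
          "sample", kept$condition[i], kept$gene[i], kept$replicate[i], rule,
          sprintf("control Cq %.1f only %d cycles above sample Cq %.1f",
                  v, round(v - kept$cq[i]), kept$cq[i]))
        drop_row[i] <- TRUE
      }
    }
  }
  kept <- kept[!drop_row, , drop = FALSE]

  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(scope = character(), condition = character(),
               gene = character(), replicate = character(),
               rule = character(), detail = character(),
               stringsAsFactors = FALSE)
  if (nrow(exclusions)) {
    warning("qc_filter excluded ", nrow(exclusions), " record group(s): ",
            paste(unique(exclusions$rule), collapse = ", "), call. = FALSE)
  }
  list(records = kept, exclusions = exclusions)
}

delta_cq <- function(records, gene, condition, reference_gene) {
  g <- records[records$gene == gene & records$condition == condition, ,
               drop = FALSE]
  r <- records[records$gene == reference_gene &
                 records$condition == condition, , drop = FALSE]
  if (!nrow(g) || !nrow(r)) {
    stop("no ", if (!nrow(g)) gene else reference_gene,
         " records for condition '", condition, "'", call. = FALSE)
  }
  ref_mean <- mean(r$cq)
  data.frame(replicate = g$replicate, delta_cq = g$cq - ref_mean,
             stringsAsFactors = FALSE)
}

#' Relative transcript abundance by the 2^-ddCq method
#'
#' Per-replicate delta-Cq (gene Cq minus the condition's mean reference-gene
#' Cq) is compared with the mean delta-Cq of the baseline (minimum
#' expression) condition; fold change is `2^-ddCq`. Per-replicate fold
#' changes are retained so downstream standard deviations can be propagated.
#'
#' @param records QC-passed Cq records.
#' @param gene target gene.
#' @param condition condition of interest.
#' @param baseline_condition the minimum-expression condition (fold change 1).
#' @param reference_gene reference gene; default `"rpoD"`.
#' @return List of class `"fold_change"` with `gene`, `condition`,
#'   `baseline`, `fold_change` (mean), and `replicates` (data.frame
#'   `replicate`, `fold_change`).
#' @export
fold_change <- function(records, gene, condition, baseline_condition,
                        reference_gene = "rpoD") {
  dc <- delta_cq(records, gene, condition, reference_gene)
  dc0 <- delta_cq(records, gene, baseline_condition, reference_gene)
  ddcq <- dc$delta_cq - mean(dc0$delta_cq)
  reps <- data.frame(replicate = dc$replicate, fold_change = 2^(-ddcq),
                     stringsAsFactors = FALSE)
  structure(list(gene = gene, condition = condition,
                 baseline = baseline_condition,
                 fold_change = 2^(-mean(ddcq)), replicates = reps),
            class = "fold_change")
}

#' Calibrated fractional sensor response from a fold change
#'
#' Linear calibration of sensor DNA occupancy between the dynamic-range
#' anchors 0.01 and 0.99. For co-repressors and de-repressors the minimum
#' expression condition anchors theta_D at 0.99 and the maximum at 0.01:
#' `theta_D = 0.99 - 0.98 * (fc_obs - 1) / (fc_max - 1)`. For activators the
#' direction reverses: `theta_DM = 0.01 + 0.98 * (fc_obs - 1) / (fc_max - 1)`.
#' Observed fold changes outside `[1, fc_max]` are clamped to the nearest
#' anchor with a warning -- outside the dynamic range, availability changes
#' without detectable change in expression.
#'
#' @param fold_change_obs observed fold change(s), relative to the minimum
#'   expression condition.
#' @param fold_change_max maximum observed fold change (the opposite
#'   boundary condition); must exceed 1.
#' @param class sensor class (see [sensor_params()]).
#' @return theta value(s) in `[0.01, 0.99]`.
#' @export
fractional_response <- function(fold_change_obs, fold_change_max, class) {
  class <- match.arg(class, sensor_classes())
  if (!is.numeric(fold_change_max) || length(fold_change_max) != 1L ||
      !is.finite(fold_change_max) || fold_change_max <= 1) {
    stop("degenerate boundary: fold_change_max must exceed 1", call. = FALSE)
  }
  fc <- fold_change_obs
  if (any(fc < 1) || any(fc > fold_change_max)) {
    warning(sprintf(
      "%d fold change(s) outside [1, %.3g] clamped to the dynamic range",
      sum(fc < 1 | fc > fold_change_max), fold_change_max), call. = FALSE)
    fc <- pmin(pmax(fc, 1), fold_change_max)
  }
  frac <- (fc - 1) / (fold_change_max - 1)
  if (class == "activator") 0.01 + 0.98 * frac else 0.99 - 0.98 * frac
}

#' Buffered metal concentration from replicate sensor responses
#'
#' Inverts each replicate's fractional response through the sensor model and
#' aggregates on the concentration scale: the estimate is the mean of the
#' per-replicate concentrations and the standard deviation is taken over the
#' same replicate concentrations (not over theta). Boundary-defining
#' conditions -- all responses at exactly 0.01 or 0.99 -- carry no standard
#' deviation. Replicates whose theta is outside the sensor's attainable
#' range are dropped with a warning and the estimate is computed from the
#' remainder.
#'
#' @param theta numeric vector of per-replicate fractional responses.
#' @param params the [sensor_params()] of the responding sensor.
#' @param condition condition label carried into the result.
#' @param constants a [thermo_constants()] object for the free-energy column.
#' @param ... passed to [invert_sensor_response()].
#' @return An `"availability_estimate"`: list with `metal`, `sensor`,
#'   `condition`, `concentration` (M, mean), `sd` (M or `NA` for boundary
#'   conditions), `delta_g` (kJ mol^-1, from the mean), `n` replicates used,
#'   and `replicate_concentrations`.
#' @export
calibrate_availability <- function(theta, params, condition = "unspecified",
                                   constants = thermo_constants(), ...) {
  stopifnot(inherits(params, "sensor_params"), is.numeric(theta),
            length(theta) >= 1)
  conc <- rep(NA_real_, length(theta))
  for (i in seq_along(theta)) {
    conc[i] <- tryCatch(invert_sensor_response(params, theta[i], ...),
                        error = function(e) NA_real_)
  }
  if (anyNA(conc)) {
    warning(sum(is.na(conc)), " replicate(s) outside the attainable range ",
            "of sensor ", params$name, " dropped", call. = FALSE)
    keep <- !is.na(conc)
    conc <- conc[keep]
    theta <- theta[keep]
  }
  if (!length(conc)) {
    stop("no replicate produced an attainable response for sensor ",
         params$name, call. = FALSE)
  }
  boundary <- all(abs(theta - 0.01) < 1e-12) || all(abs(theta - 0.99) < 1e-12)
  est <- mean(conc)
  structure(list(
    metal = params$metal, sensor = params$name, condition = condition,
    concentration = est,
    sd = if (boundary || length(conc) < 2) NA_real_ else stats::sd(conc),
    delta_g = delta_g(est, constants),
    n = length(conc),
    replicate_concentrations = conc
  ), class = "availability_estimate")
}

#' @export
print.availability_estimate <- function(x, ...) {
  cat(sprintf("<availability_estimate> %s via %s, %s\n",
              x$metal, x$sensor, x$condition))
  cat(sprintf("  [M]buffered = %.3g M%s, dG = %.1f kJ/mol (n = %d)\n",
              x$concentration,
              if (is.na(x$sd)) "" else sprintf(" (SD %.2g)", x$sd),
              x$delta_g, x$n))
  invisible(x)
}

#' Two-sensor zinc midpoint
#'
#' Zinc availability is bracketed by two sensors (Zur via znuA, ZntR via
#' zntA). The single availability used by the calculators is the log-scale
#' midpoint -- the geometric mean -- of the two sensor-specific means.
#'
#' @param zur_estimate,zntr_estimate `"availability_estimate"` objects for
#'   Zn2+ in the same condition.
#' @param constants a [thermo_constants()] object.
#' @return An `"availability_estimate"` labelled sensor `"Midpoint"` with no
#'   standard deviation.
#' @export
zinc_midpoint <- function(zur_estimate, zntr_estimate,
                          constants = thermo_constants()) {
  stopifnot(inherits(zur_estimate, "availability_estimate"),
            inherits(zntr_estimate, "availability_estimate"))
  if (zur_estimate$metal != "Zn2+" || zntr_estimate$metal != "Zn2+") {
    stop("zinc_midpoint requires two Zn2+ estimates", call. = FALSE)
  }
  if (zur_estimate$condition != zntr_estimate$condition) {
    stop("condition mismatch: '", zur_estimate$condition, "' vs '",
         zntr_estimate$condition, "'", call. = FALSE)
  }
  mid <- sqrt(zur_estimate$concentration * zntr_estimate$concentration)
  structure(list(
    metal = "Zn2+", sensor = "Midpoint",
    condition = zur_estimate$condition,
    concentration = mid, sd = NA_real_,
    delta_g = delta_g(mid, constants),
    n = zur_estimate$n + zntr_estimate$n,
    replicate_concentrations = numeric()
  ), class = "availability_estimate")
}

#' Run the full Cq-to-availability calibration for one sensor
#'
#' Convenience pipeline: per-replicate fold changes for the condition of
#' interest, the maximum fold change from the declared maximum-expression
#' condition, fractional responses, and inversion through the sensor model.
#'
#' @param records QC-passed Cq records.
#' @param params [sensor_params()] of the sensor regulating `gene`.
#' @param gene regulated transcript.
#' @param condition condition to estimate.
#' @param min_condition minimum-expression (baseline) condition.
#' @param max_condition maximum-expression condition.
#' @param reference_gene reference gene; default `"rpoD"`.
#' @param ... passed to [calibrate_availability()].
#' @return An `"availability_estimate"`.
#' @export
calibrate_sensor <- function(records, params, gene, condition, min_condition,
                             max_condition, reference_gene = "rpoD", ...) {
  fc_max <- fold_change(records, gene, max_condition, min_condition,
                        reference_gene)$fold_change
  fc <- fold_change(records, gene, condition, min_condition, reference_gene)
  theta <- fractional_response(fc$replicates$fold_change, fc_max,
                               params$class)
  calibrate_availability(theta, params, condition = condition, ...)
}
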