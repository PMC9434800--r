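AVOGADRO <- 6.02214076e23

#' Default sensor classification and gene map
#'
#' The seven metalloregulators, their sensor class, cognate metal, and the
#' regulated transcript monitored by qPCR. MntR, Fur, Zur, and NikR are
#' co-repressors (metalated sensor represses), RcnR is a de-repressor
#' (apo sensor represses, metal releases it), and ZntR and CueR are
#' activators (metalated sensor activates).
#'
#' @return data.frame with columns `sensor`, `gene`, `metal`, `class`.
#' @export
sensor_gene_map <- function() {
  data.frame(
    sensor = c("MntR", "Fur", "RcnR", "NikR", "Zur", "ZntR", "CueR"),
    gene   = c("mntS", "fepD", "rcnA", "nikA", "znuA", "zntA", "copA"),
    metal  = c("Mn2+", "Fe2+", "Co2+", "Ni2+", "Zn2+", "Zn2+", "Cu1+"),
    class  = c("co-repressor", "co-repressor", "de-repressor", "co-repressor",
               "co-repressor", "activator", "activator"),
    stringsAsFactors = FALSE
  )
}

#' Reference genes accepted by the qPCR pipeline
#' @return Character vector of reference gene names.
#' @export
reference_genes <- function() c("rpoD", "gyrA")

sensor_classes <- function() c("co-repressor", "de-repressor", "activator")

#' Thermodynamic parameter set of a DNA-binding metal sensor
#'
#' Bundles the constants that define a metalloregulator's response curve:
#' the dissociation constant of the tightest allosteric metal site, the
#' operator DNA affinities of the apo and metalated sensor, sensor abundance
#' (molecules per cell) at low and at elevated metal, the number of operator
#' targets per cell, and the cell volume used to convert molecules to molar.
#'
#' @param name sensor name (e.g. `"MntR"`).
#' @param metal cognate metal symbol, one of [metal_ions()].
#' @param class sensor class: `"co-repressor"`, `"de-repressor"` or
#'   `"activator"`.
#' @param k_metal metal dissociation constant of the allosteric site (M).
#' @param k_dna_apo apo-sensor--operator dissociation constant (M).
#' @param k_dna_holo metalated-sensor--operator dissociation constant (M).
#' @param abundance_low,abundance_high sensor molecules per cell at low and
#'   at elevated metal.
#' @param n_targets number of operator DNA sites per cell (integer >= 1).
#' @param cell_volume cell volume in litres; defaults to 1e-15 L.
#' @param provenance free-text note on where the constants come from.
#' @return An object of class `"sensor_params"` (a named list).
#' @details For co-repressors and activators metal binding must tighten DNA
#'   binding (`k_dna_holo < k_dna_apo`); for de-repressors the apo sensor is
#'   the tight binder (`k_dna_apo < k_dna_holo`). `abundance_low >
#'   abundance_high` is allowed but flagged with a warning.
#' @export
sensor_params <- function(name, metal, class, k_metal, k_dna_apo, k_dna_holo,
                          abundance_low, abundance_high, n_targets,
                          cell_volume = 1e-15, provenance = "unspecified") {
  class <- match.arg(class, sensor_classes())
  assert_metal(metal)
  num <- c(k_metal = k_metal, k_dna_apo = k_dna_apo, k_dna_holo = k_dna_holo,
           abundance_low = abundance_low, abundance_high = abundance_high,
           cell_volume = cell_volume)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all sensor constants must be strictly positive and finite (",
         name, ")", call. = FALSE)
  }
  if (n_targets < 1 || n_targets != round(n_targets)) {
    stop("n_targets must be an integer >= 1 (", name, ")", call. = FALSE)
  }
  if (abundance_low > abundance_high) {
    warning("sensor ", name, ": abundance_low > abundance_high; ",
            "abundances flagged as inverted", call. = FALSE)
  }
  if (class %in% c("co-repressor", "activator") && !(k_dna_holo < k_dna_apo)) {
    stop("sensor ", name, " (", class, "): metal must tighten DNA binding ",
         "(k_dna_holo < k_dna_apo)", call. = FALSE)
  }
  if (class == "de-repressor" && !(k_dna_apo < k_dna_holo)) {
    stop("sensor ", name, " (de-repressor): apo sensor must bind DNA more ",
         "tightly (k_dna_apo < k_dna_holo)", call. = FALSE)
  }
  structure(
    list(name = name, metal = metal, class = class,
         k_metal = k_metal, k_dna_apo = k_dna_apo, k_dna_holo = k_dna_holo,
         abundance_low = abundance_low, abundance_high = abundance_high,
         n_targets = as.integer(n_targets), cell_volume = cell_volume,
         provenance = provenance),
    class = "sensor_params"
  )
}

#' @export
print.sensor_params <- function(x, ...) {
  cat(sprintf("<sensor_params> %s (%s, %s)\n", x$name, x$metal, x$class))
  cat(sprintf("  K_metal    = %.3g M\n", x$k_metal))
  cat(sprintf("  K_DNA apo  = %.3g M, holo = %.3g M\n",
              x$k_dna_apo, x$k_dna_holo))
  cat(sprintf("  abundance  = %g..%g molecules/cell, %d target(s), V = %.3g L\n",
              x$abundance_low, x$abundance_high, x$n_targets, x$cell_volume))
  cat(sprintf("  provenance : %s\n", x$provenance))
  invisible(x)
}

#' Read a set of sensor parameter records from YAML
#'
#' Expects a top-level `sensors:` list, one record per sensor with the
#' [sensor_params()] fields plus a `class` tag and optional `provenance`.
#' A packaged synthetic example is available via
#' `system.file("extdata", "sensors_synthetic.yaml", package = "metalation")`.
#'
#' @param path path to a YAML (or JSON) file.
#' @return Named list of `sensor_params` objects, keyed by sensor name.
#' @export
read_sensor_params <- function(path) {
  if (!file.exists(path)) stop("sensor parameter file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  recs <- raw$sensors
  if (is.null(recs)) stop("no `sensors:` section in ", path, call. = FALSE)
  out <- lapply(recs, function(r) {
    needed <- c("name", "metal", "class", "k_metal", "k_dna_apo",
                "k_dna_holo", "abundance_low", "abundance_high", "n_targets")
    missing <- setdiff(needed, names(r))
    if (length(missing)) {
      stop("sensor record in ", path, " missing field(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    sensor_params(
      name = r$name, metal = r$metal, class = r$class,
      k_metal = as.numeric(r$k_metal),
      k_dna_apo = as.numeric(r$k_dna_apo),
      k_dna_holo = as.numeric(r$k_dna_holo),
      abundance_low = as.numeric(r$abundance_low),
      abundance_high = as.numeric(r$abundance_high),
      n_targets = as.numeric(r$n_targets),
      cell_volume = if (is.null(r$cell_volume)) 1e-15
                    else as.numeric(r$cell_volume),
      provenance = if (is.null(r$provenance)) "unspecified" else r$provenance
    )
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

molecules_to_molar <- function(n, cell_volume) {
  n / (AVOGADRO * cell_volume)
}
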