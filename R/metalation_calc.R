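#' Condition-specific metal availability presets
#'
#' Loads one of the packaged buffered-metal availability presets -- the
#' concentrations estimated for E. coli JM109 (DE3) grown in LB aerobically,
#' anaerobically, or after H2O2 exposure -- or builds a custom preset from a
#' named concentration vector. The packaged zinc entry is the two-sensor
#' midpoint; the Zur-only and ZntR-only values are available through
#' `zinc = "zur"` or `zinc = "zntr"`.
#'
#' @param condition `"aerobic"`, `"anaerobic"`, `"h2o2"`, or `"custom"`.
#' @param concentrations for `condition = "custom"`: named numeric vector of
#'   molar concentrations keyed by metal symbol (see [metal_ions()]).
#' @param zinc which packaged zinc availability to use: `"midpoint"`
#'   (default), `"zur"`, or `"zntr"`.
#' @param constants a [thermo_constants()] object for derived free energies.
#' @param provenance free-text provenance note for custom presets.
#' @return An `"availability_preset"`: list with `condition`, a data.frame
#'   `metals` (columns `metal`, `concentration`, `sd`, `delta_g`), and
#'   `provenance`.
#' @examples
#' availability_preset("anaerobic")
#' @export
availability_preset <- function(condition = c("aerobic", "anaerobic", "h2o2",
                                              "custom"),
                                concentrations = NULL,
                                zinc = c("midpoint", "zur", "zntr"),
                                constants = thermo_constants(),
                                provenance = NULL) {
  condition <- match.arg(condition)
  zinc <- match.arg(zinc)
  if (condition == "custom") {
    if (is.null(concentrations) || is.null(names(concentrations))) {
      stop("custom presets need a named concentration vector", call. = FALSE)
    }
    assert_metal(names(concentrations))
    if (any(!is.finite(concentrations)) || any(concentrations <= 0)) {
      stop("preset concentrations must be positive and finite", call. = FALSE)
    }
    metals <- data.frame(metal = names(concentrations),
                         concentration = as.numeric(concentrations),
                         sd = NA_real_, stringsAsFactors = FALSE)
    prov <- if (is.null(provenance)) "custom" else provenance
  } else {
    path <- system.file("extdata", "availability_presets.yaml",
                        package = "metalation")
    raw <- yaml::read_yaml(path)
    rec <- raw$presets[[condition]]
    if (is.null(rec)) stop("packaged preset '", condition, "' not found",
                           call. = FALSE)
    metals <- do.call(rbind, lapply(rec$metals, function(m) {
      conc <- as.numeric(m$concentration)
      if (m$metal == "Zn2+" && zinc != "midpoint") {
        alt <- m[[paste0("zinc_", zinc)]]
        conc <- as.numeric(alt$concentration)
        m$sd <- alt$sd
      }
      data.frame(metal = m$metal, concentration = conc,
                 sd = if (is.null(m$sd)) NA_real_ else as.numeric(m$sd),
                 stringsAsFactors = FALSE)
    }))
    prov <- raw$provenance
  }
  metals <- metals[order(match(metals$metal, metal_ions())), , drop = FALSE]
  rownames(metals) <- NULL
  metals$delta_g <- delta_g(metals$concentration, constants)
  structure(list(condition = condition, metals = metals, provenance = prov),
            class = "availability_preset")
}

#' @export
print.availability_preset <- function(x, ...) {
  cat(sprintf("<availability_preset> %s\n", x$condition))
  df <- x$metals
  df$concentration <- sprintf("%.2g M", df$concentration)
  df$delta_g <- sprintf("%.1f kJ/mol", df$delta_g)
  df$sd <- ifelse(is.na(x$metals$sd), "-", sprintf("%.1g", x$metals$sd))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Override availabilities in a preset ("what-if" simulation)
#'
#' Returns a new preset with selected metal concentrations replaced,
#' free energies re-derived, and provenance marked custom -- the programmatic
#' equivalent of typing concentrations into the editable column of the
#' calculator.
#'
#' @param base an [availability_preset()].
#' @param overrides named numeric vector of molar concentrations; an empty
#'   vector returns the preset unchanged.
#' @param constants a [thermo_constants()] object.
#' @return An `"availability_preset"`.
#' @export
whatif_availability <- function(base, overrides,
                                constants = thermo_constants()) {
  stopifnot(inherits(base, "availability_preset"))
  if (!length(overrides)) return(base)
  if (is.null(names(overrides))) {
    stop("overrides must be named by metal symbol", call. = FALSE)
  }
  assert_metal(names(overrides))
  if (any(!is.finite(overrides)) || any(overrides <= 0)) {
    stop("override concentrations must be positive and finite",
         call. = FALSE)
  }
  metals <- base$metals
  for (m in names(overrides)) {
    i <- match(m, metals$metal)
    if (is.na(i)) {
      metals <- rbind(metals, data.frame(
        metal = m, concentration = overrides[[m]], sd = NA_real_,
        delta_g = NA_real_, stringsAsFactors = FALSE))
    } else {
      metals$concentration[i] <- overrides[[m]]
      metals$sd[i] <- NA_real_
    }
  }
  metals <- metals[order(match(metals$metal, metal_ions())), , drop = FALSE]
  rownames(metals) <- NULL
  metals$delta_g <- delta_g(metals$concentration, constants)
  structure(list(condition = "custom", metals = metals,
                 provenance = paste0("custom (from ", base$condition, ")")),
            class = "availability_preset")
}

#' Metal affinities of a protein or other molecule
#'
#' @param kd named numeric vector of dissociation constants (M), keyed by
#'   metal symbol; only the metals present (and enabled) enter the
#'   competition. `NA` entries are treated as disabled.
#' @param name molecule name for reporting.
#' @param enabled optional named logical vector toggling metals off without
#'   removing their K_D (mirrors the calculator's toggle switches).
#' @return A `"protein_affinities"`: list with `name` and data.frame
#'   `affinities` (`metal`, `kd`, `enabled`).
#' @examples
#' protein_affinities(c("Ni2+" = 6e-14, "Zn2+" = 2.2e-11), name = "HypB")
#' @export
protein_affinities <- function(kd, name = "molecule", enabled = NULL) {
  if (is.null(names(kd))) stop("kd must be named by metal symbol",
                               call. = FALSE)
  assert_metal(names(kd))
  en <- !is.na(kd)
  if (!is.null(enabled)) {
    assert_metal(names(enabled))
    en[names(enabled)] <- en[names(enabled)] & enabled
  }
  if (any(en & (kd <= 0 | !is.finite(kd)))) {
    stop("enabled dissociation constants must be positive and finite",
         call. = FALSE)
  }
  aff <- data.frame(metal = names(kd), kd = as.numeric(kd),
                    enabled = unname(en), stringsAsFactors = FALSE)
  aff <- aff[order(match(aff$metal, metal_ions())), , drop = FALSE]
  rownames(aff) <- NULL
  structure(list(name = name, affinities = aff),
            class = "protein_affinities")
}

#' Read molecule affinities from TSV/CSV or YAML
#'
#' Tabular input needs columns `metal`, `kd_molar`, and optionally `enabled`
#' (logical). YAML input needs `name:` and a `metals:` map of
#' metal-symbol: K_D pairs.
#'
#' @param path input file path.
#' @param name molecule name; defaults to the file stem (tabular input).
#' @return A [protein_affinities()] object.
#' @export
read_affinities <- function(path, name = NULL) {
  if (!file.exists(path)) stop("affinity file not found: ", path,
                               call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    kd <- vapply(raw$metals, as.numeric, numeric(1))
    return(protein_affinities(kd, name = raw$name %||% "molecule"))
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  missing <- setdiff(c("metal", "kd_molar"), names(df))
  if (length(missing)) {
    stop("affinity table ", path, " missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  kd <- stats::setNames(as.numeric(df$kd_molar), df$metal)
  enabled <- if (!is.null(df$enabled)) {
    stats::setNames(as.logical(df$enabled), df$metal)
  }
  if (is.null(name)) name <- sub("\\.[^.]+$", "", basename(path))
  protein_affinities(kd, name = name, enabled = enabled)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Competitive metal occupancy of a single site
#'
#' The calculator core. For each enabled metal the availability-to-affinity
#' ratio `r_i = [M_i] / K_D,i` measures how strongly the molecule competes
#' with the intracellular buffer for that metal; inter-metal competition at
#' a single site of maximum stoichiometry 1 then gives
#' `theta_i = r_i / (1 + sum_j r_j)`. Equivalently, with
#' `ddG_i = RT ln K_D,i - RT ln [M_i]` (free energy of the half-saturated
#' complex minus the availability free energy),
#' `theta_i = exp(-ddG_i/RT) / (1 + sum_j exp(-ddG_j/RT))`; both forms are
#' computed and must agree. The "1 +" term is the unmetalated site, which
#' embodies competition from the buffer; the buffered pool itself is assumed
#' undepleted by the molecule of interest.
#'
#' @param affinities a [protein_affinities()] object.
#' @param preset an [availability_preset()].
#' @param constants a [thermo_constants()] object.
#' @return A `"metalation_result"`: list with `molecule`, `condition`, a
#'   data.frame `metals` (columns `metal`, `kd`, `concentration`,
#'   `delta_g_protein`, `delta_g_available`, `delta_delta_g`, `occupancy`,
#'   `occupancy_pct`), and `total_occupancy`.
#' @examples
#' hypb <- protein_affinities(c("Ni2+" = 6e-14, "Zn2+" = 2.2e-11), "HypB")
#' metal_occupancy(hypb, availability_preset("anaerobic"))
#' @export
metal_occupancy <- function(affinities, preset,
                            constants = thermo_constants()) {
  stopifnot(inherits(affinities, "protein_affinities"),
            inherits(preset, "availability_preset"))
  aff <- affinities$affinities[affinities$affinities$enabled, , drop = FALSE]
  if (!nrow(aff)) {
    metals <- data.frame(metal = character(), kd = numeric(),
                         concentration = numeric(),
                         delta_g_protein = numeric(),
                         delta_g_available = numeric(),
                         delta_delta_g = numeric(), occupancy = numeric(),
                         occupancy_pct = numeric(), stringsAsFactors = FALSE)
    return(structure(list(molecule = affinities$name,
                          condition = preset$condition, metals = metals,
                          total_occupancy = 0), class = "metalation_result"))
  }
  i <- match(aff$metal, preset$metals$metal)
  if (anyNA(i)) {
    stop("no availability in preset '", preset$condition, "' for enabled ",
         "metal(s): ", paste(aff$metal[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  conc <- preset$metals$concentration[i]
  r <- conc / aff$kd
  occupancy <- r / (1 + sum(r))

  dg_protein <- delta_g(aff$kd, constants)
  dg_avail <- delta_g(conc, constants)
  ddg <- dg_protein - dg_avail
  w <- exp(-ddg / constants$RT)
  occupancy_g <- w / (1 + sum(w))
  if (any(abs(occupancy - occupancy_g) >
          1e-10 * pmax(occupancy, .Machine$double.xmin))) {
    stop("internal inconsistency: concentration-form and free-energy-form ",
         "occupancies disagree", call. = FALSE)
  }

  metals <- data.frame(
    metal = aff$metal, kd = aff$kd, concentration = conc,
    delta_g_protein = dg_protein, delta_g_available = dg_avail,
    delta_delta_g = ddg, occupancy = occupancy,
    occupancy_pct = 100 * occupancy, stringsAsFactors = FALSE)
  structure(list(molecule = affinities$name, condition = preset$condition,
                 metals = metals, total_occupancy = sum(occupancy)),
            class = "metalation_result")
}

#' @export
print.metalation_result <- function(x, ...) {
  cat(sprintf("<metalation_result> %s, %s conditions\n",
              x$molecule, x$condition))
  if (!nrow(x$metals)) {
    cat("  (no metals enabled)\n")
    return(invisible(x))
  }
  df <- data.frame(
    metal = metal_label(x$metals$metal),
    K_D = sprintf("%.2g M", x$metals$kd),
    dG_protein = sprintf("%.1f", x$metals$delta_g_protein),
    dG_available = sprintf("%.1f", x$metals$delta_g_available),
    ddG = sprintf("%.1f", x$metals$delta_delta_g),
    occupancy = sprintf("%.1f%%", x$metals$occupancy_pct),
    stringsAsFactors = FALSE)
  print(df, row.names = FALSE)
  cat(sprintf("  total occupancy: %.1f%% (free energies kJ/mol)\n",
              100 * x$total_occupancy))
  invisible(x)
}

#' Render a metalation result as a table, TSV, or JSON
#'
#' @param result a [metal_occupancy()] result.
#' @param format `"data.frame"` (default), `"tsv"`, or `"json"`.
#' @param path optional output file for `"tsv"`/`"json"`; when `NULL` the
#'   rendered text is returned as a character string.
#' @return A data.frame, or rendered text (invisibly `path` when written).
#' @export
report_metalation <- function(result, format = c("data.frame", "tsv", "json"),
                              path = NULL) {
  stopifnot(inherits(result, "metalation_result"))
  format <- match.arg(format)
  df <- result$metals
  df$occupancy_pct <- round(df$occupancy_pct, 1)
  if (format == "data.frame") return(df)
  if (format == "tsv") {
    txt <- paste(utils::capture.output(
      utils::write.table(df, sep = "\t", quote = FALSE, row.names = FALSE)),
      collapse = "\n")
  } else {
    txt <- as.character(jsonlite::toJSON(list(
      molecule = result$molecule, condition = result$condition,
      metals = df, total_occupancy = result$total_occupancy),
      dataframe = "rows", auto_unbox = TRUE, digits = NA))
  }
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}
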