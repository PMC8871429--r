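#' Write osmotic deswelling tables to CSV
#'
#' Self-describing CSV with columns `phi, pressure_Pa, pressure_kind, G_s_Pa,
#' c_NaCl_mM, c_CaCl2_mM, T_K, uncertainty_Pa`. One file can hold several
#' conditions; readers group rows by (c_NaCl_mM, c_CaCl2_mM, T_K).
#'
#' @param curves a single [osmotic_curve()] or list of them.
#' @param path output file path.
#' @param G_s per-curve shear modulus (Pa): scalar, or list of per-point
#'   vectors parallel to `curves`.
#' @return `path`, invisibly.
#' @export
write_osmotic_table <- function(curves, path, G_s = NA_real_) {
  if (inherits(curves, "osmotic_curve")) curves <- list(curves)
  if (inherits(curves, "salt_sweep")) {
    G_s <- lapply(curves, `[[`, "G_s")
    curves <- lapply(curves, `[[`, "curve")
  }
  rows <- lapply(seq_along(curves), function(i) {
    cu <- curves[[i]]
    stopifnot(inherits(cu, "osmotic_curve"))
    cond <- cu$condition
    g <- if (is.list(G_s)) G_s[[i]] else G_s
    data.frame(
      phi = cu$phi,
      pressure_Pa = cu$pressure,
      pressure_kind = cu$pressure_kind,
      G_s_Pa = rep_len(g, length(cu$phi)),
      c_NaCl_mM = rep_len(cond$c_NaCl %||% NA_real_, length(cu$phi)),
      c_CaCl2_mM = rep_len(cond$control %||% cond$c_CaCl2 %||% NA_real_,
                           length(cu$phi)),
      T_K = rep_len(cond$T_K %||% NA_real_, length(cu$phi)),
      uncertainty_Pa = if (is.null(cu$uncertainty)) NA_real_ else cu$uncertainty
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.schema_error <- function(msg) {
  stop(structure(class = c("gelosmo_schema_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}
.parse_error <- function(msg) {
  stop(structure(class = c("gelosmo_parse_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Read osmotic deswelling tables
#'
#' Reads the CSV schema written by [write_osmotic_table()], converts declared
#' bench units to SI, groups rows by condition and returns one
#' [osmotic_curve()] per condition. Malformed numeric cells are reported with
#' their line number.
#'
#' @param path CSV file path.
#' @param pressure_unit `"Pa"` (default) or `"kPa"`; pressures (and
#'   uncertainties, moduli) are multiplied by 1000 when `"kPa"` is declared.
#' @return list of [osmotic_curve()]; each carries `G_s` per point in its
#'   condition metadata. Empty file returns an empty list with a warning.
#' @export
read_osmotic_table <- function(path, pressure_unit = c("Pa", "kPa")) {
  pressure_unit <- match.arg(pressure_unit)
  if (!file.exists(path)) .schema_error(paste("file not found:", path))
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) .parse_error(conditionMessage(e)))
  if (nrow(df) == 0L) {
    warning("empty osmotic table: ", path)
    return(list())
  }
  mandatory <- c("phi", "pressure_Pa", "pressure_kind")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0L) {
    .schema_error(paste("missing mandatory column(s):",
                        paste(missing_cols, collapse = ", ")))
  }
  for (col in intersect(c("phi", "pressure_Pa", "G_s_Pa", "uncertainty_Pa"),
                        names(df))) {
    v <- df[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & v != "" & v != "NA")
    if (length(bad) > 0L) {
      .parse_error(sprintf("non-numeric value '%s' in column '%s' at line %d",
                           v[bad[1]], col, bad[1] + 1L))
    }
    df[[col]] <- num
  }
  mult <- if (pressure_unit == "kPa") 1000 else 1
  bad_phi <- which(!is.finite(df$phi) | df$phi <= 0 | df$phi >= 1)
  if (length(bad_phi) > 0L) {
    .parse_error(sprintf("phi out of (0,1) at line %d", bad_phi[1] + 1L))
  }
  for (opt in c("c_NaCl_mM", "c_CaCl2_mM", "T_K", "G_s_Pa", "uncertainty_Pa")) {
    if (!opt %in% names(df)) df[[opt]] <- NA_real_
  }
  na_safe <- function(v) ifelse(is.na(v), "na", format(v, digits = 12))
  key <- paste(na_safe(df$c_NaCl_mM), na_safe(df$c_CaCl2_mM), na_safe(df$T_K),
               sep = "|")
  key <- factor(key, levels = unique(key))  # preserve file order
  out <- lapply(split(df, key), function(g) {
    unc <- g$uncertainty_Pa * mult
    osmotic_curve(
      g$phi, g$pressure_Pa * mult,
      pressure_kind = unique(g$pressure_kind)[1],
      condition = list(c_NaCl = g$c_NaCl_mM[1], c_CaCl2 = g$c_CaCl2_mM[1],
                       T_K = g$T_K[1], G_s = g$G_s_Pa * mult),
      uncertainty = if (all(is.finite(unc))) unc else NULL)
  })
  names(out) <- NULL
  out
}

#' Write a reduced SANS profile as 3-column ASCII
#'
#' Whitespace-separated `q I dI` with '#' header comments, the conventional
#' reduced-data exchange format.
#'
#' @param profile a [sans_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sans_profile <- function(profile, path) {
  stopifnot(inherits(profile, "sans_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# q_invA I_invcm dI_invcm", con)
  dI <- profile$dI %||% rep(NA_real_, length(profile$q))
  writeLines(sprintf("%.10g %.10g %.10g", profile$q, profile$I, dI), con)
  invisible(path)
}

#' Read a reduced SANS profile
#'
#' Accepts whitespace- or comma-separated ASCII with 2 or 3 numeric columns
#' (q, I[, dI]); lines starting with '#' are skipped. q must be positive; by
#' default unsorted q is an error.
#'
#' @param path input path.
#' @param sort_q if `TRUE`, sort by q with a warning instead of erroring.
#' @return a [sans_profile()]; `dI` is `NULL` for 2-column files.
#' @export
read_sans_profile <- function(path, sort_q = FALSE) {
  if (!file.exists(path)) .schema_error(paste("file not found:", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) .schema_error("empty SANS profile (no data rows)")
  rows <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) < 2L || any(is.na(vals[1:2]))) {
      .parse_error(sprintf("malformed SANS row at line %d: '%s'",
                           lineno[i], lines[i]))
    }
    vals
  })
  ncols <- min(vapply(rows, length, integer(1)))
  m <- do.call(rbind, lapply(rows, function(r) r[seq_len(max(ncols, 2L))]))
  q <- m[, 1]; I <- m[, 2]
  dI <- if (ncols >= 3L && !all(is.na(m[, 3]))) m[, 3] else NULL
  neg <- which(q <= 0)
  if (length(neg) > 0L) {
    .parse_error(sprintf("non-positive q at line %d", lineno[neg[1]]))
  }
  if (any(diff(q) <= 0)) {
    if (!sort_q) {
      .parse_error("q not strictly increasing (use sort_q = TRUE to sort)")
    }
    warning("sorting SANS profile by q")
    o <- order(q)
    q <- q[o]; I <- I[o]
    if (!is.null(dI)) dI <- dI[o]
  }
  sans_profile(q, I, dI)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages on file or in-memory inputs: decompose swelling
#' pressure -> fit virial coefficients per condition -> equilibrium swelling
#' and volume transition along the condition grid -> longitudinal modulus ->
#' SANS fit -> osmotic/scattering consistency. Stages whose inputs are absent
#' are marked `"skipped"`. Deterministic given config and seed.
#'
#' @param osmotic either a path to a CSV table or a list as returned by
#'   [generate_salt_sweep()]; `NULL` skips the osmotic stages.
#' @param sans either a path to a reduced profile or a [sans_profile()];
#'   `NULL` skips the scattering stage.
#' @param config named list of options: `C`, `phi_ref` (elastic scaling used
#'   when per-point moduli are absent), `fixed_charge_per_monomer`,
#'   `jump_threshold`, `fit_variant` (`"rod"`/`"oz"`),
#'   `include_elastic_derivative`, `contrast`, `phi_sans` (volume fraction of
#'   the SANS sample), `consistency_tolerance`.
#' @param solvent a [solvent_spec()].
#' @return object of class `analysis_report`: per-stage results and a
#'   `warnings` character vector; serialize with [write_report()].
#' @export
run_pipeline <- function(osmotic = NULL, sans = NULL, config = list(),
                         solvent = solvent_spec()) {
  cfg <- utils::modifyList(
    list(C = NULL, phi_ref = 0.05, fixed_charge_per_monomer = 0,
         background_NaCl = 0, jump_threshold = 2, fit_variant = "rod",
         include_elastic_derivative = FALSE, contrast = NULL,
         phi_sans = NULL, consistency_tolerance = 0.5),
    config)
  report <- list(config = cfg, stages = list(), warnings = character(0))

  conditions <- NULL
  if (!is.null(osmotic)) {
    if (is.character(osmotic)) {
      curves <- read_osmotic_table(osmotic)
      conditions <- lapply(curves, function(cu) {
        list(control = cu$condition$c_CaCl2 %||% NA_real_, curve = cu,
             G_s = cu$condition$G_s, model = NULL)
      })
    } else {
      conditions <- osmotic
    }
    fits <- lapply(conditions, function(cond) {
      cu <- cond$curve
      g <- cond$G_s
      if (is.null(g) || all(!is.finite(g))) {
        if (is.null(cfg$C)) {
          .schema_error("no shear modulus available: supply per-point G_s or config$C")
        }
        g <- list(C = cfg$C, phi_ref = cfg$phi_ref)
      }
      ions <- if (!is.null(cond$model)) {
        cond$model$ions
      } else if (cfg$fixed_charge_per_monomer > 0) {
        ca <- cond$control %||% 0
        if (!is.finite(ca)) ca <- 0
        salts <- data.frame(species = c("Na", "Cl", "Ca"), z = c(1, -1, 2),
                            conc = c(cfg$background_NaCl,
                                     cfg$background_NaCl + 2 * ca, ca))
        ionic_condition(salts, cfg$fixed_charge_per_monomer)
      } else NULL
      mix <- decompose_swelling_pressure(cu, g, ions, solvent)
      vf <- fit_virial_coefficients(mix, solvent)
      list(control = cond$control, virial = vf)
    })
    report$stages$virial_fits <- fits

    controls <- vapply(fits, `[[`, numeric(1), "control")
    if (length(fits) >= 4L && all(is.finite(controls)) &&
        !is.null(cfg$C)) {
      A2s <- vapply(fits, function(f) f$virial$A2, numeric(1))
      A3s <- vapply(fits, function(f) f$virial$A3, numeric(1))
      model_fun <- function(ctrl) {
        A2 <- stats::approx(controls, A2s, xout = ctrl, rule = 2)$y
        A3 <- stats::approx(controls, A3s, xout = ctrl, rule = 2)$y
        ions <- if (cfg$fixed_charge_per_monomer > 0) {
          salts <- data.frame(species = c("Na", "Cl", "Ca"), z = c(1, -1, 2),
                              conc = c(cfg$background_NaCl,
                                       cfg$background_NaCl + 2 * ctrl, ctrl))
          ionic_condition(salts, cfg$fixed_charge_per_monomer)
        } else NULL
        gel_model(A2, A3, C = cfg$C, phi_ref = cfg$phi_ref,
                  ions = ions, solvent = solvent)
      }
      tr <- tryCatch(
        detect_volume_transition(model_fun, controls,
                                 jump_threshold = cfg$jump_threshold),
        error = function(e) e)
      if (inherits(tr, "error")) {
        report$warnings <- c(report$warnings,
                             paste("transition stage:", conditionMessage(tr)))
      } else {
        report$stages$transition <- tr
      }
    } else {
      report$stages$transition <- "skipped"
    }
  } else {
    report$stages$virial_fits <- "skipped"
    report$stages$transition <- "skipped"
  }

  if (!is.null(sans)) {
    profile <- if (is.character(sans)) read_sans_profile(sans) else sans
    sfit <- fit_sans_profile(profile, variant = cfg$fit_variant)
    report$stages$sans_fit <- sfit
    can_consist <- !is.null(cfg$contrast) && !is.null(cfg$phi_sans) &&
      !is.null(conditions) && !is.null(cfg$C)
    if (can_consist) {
      vf1 <- report$stages$virial_fits[[1]]$virial
      gs <- shear_modulus_scaling(cfg$phi_sans, cfg$C, cfg$phi_ref)
      mos <- longitudinal_modulus(
        cfg$phi_sans, vf1$A2, vf1$A3, gs, solvent,
        include_elastic_derivative = cfg$include_elastic_derivative)
      osm <- osmotic_amplitude(cfg$phi_sans, mos, cfg$contrast, solvent)
      report$stages$consistency <-
        consistency_check(sfit$dyn_amplitude, osm,
                          tolerance = cfg$consistency_tolerance)
    } else {
      report$stages$consistency <- "skipped"
    }
  } else {
    report$stages$sans_fit <- "skipped"
    report$stages$consistency <- "skipped"
  }
  class(report) <- "analysis_report"
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    if (identical(st, "skipped")) {
      cat(sprintf("  %s: skipped\n", nm))
    } else {
      cat(sprintf("  %s: done\n", nm))
    }
  }
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' @param report an `analysis_report` from [run_pipeline()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      x[!vapply(x, is.function, logical(1))]
    } else if (is.function(x)) NULL else x
  }
  jsonlite::write_json(strip(unclass(report)), path, auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")
  invisible(path)
}
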