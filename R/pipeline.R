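#' Build a pipeline run configuration
#'
#' Collects every knob of an end-to-end run. Two input modes:
#' \itemize{
#'   \item file mode: `cells_csv` (per-cell export) and `clinical_csv`
#'     (patient-level table with arm, histology and logical MPR/ORR/pCR
#'     columns);
#'   \item simulation mode: `simulate = cohort_sim_config(...)`, which
#'     generates both.
#' }
#'
#' @param cells_csv,clinical_csv Input paths (file mode).
#' @param simulate A [cohort_sim_config()] (simulation mode), or `NULL`.
#' @param out_dir Output directory for the report bundle.
#' @param radius Proximity radius in micrometres (> 0; default 30).
#' @param aggregation Core-to-patient aggregation method.
#' @param rules Phenotype rules (default CAF/TAEC gating).
#' @param mw_mode Mann-Whitney mode for the comparison tables.
#' @param dichotomize_rule `"median"` or a numeric threshold, for the
#'   univariate odds-ratio table.
#' @param roc_arm,roc_histology Subset in which metrics are evaluated as MPR
#'   predictors by ROC and odds ratio.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cells_csv = NULL, clinical_csv = NULL, simulate = NULL,
                       out_dir, radius = 30, aggregation = "mean",
                       rules = default_phenotype_rules(), mw_mode = "auto",
                       dichotomize_rule = "median",
                       roc_arm = "NAIC", roc_histology = "SCC") {
  stopifnot(is.numeric(radius), radius > 0)
  if (is.null(simulate)) {
    for (p in c(cells_csv, clinical_csv)) {
      if (is.null(p) || !file.exists(p)) {
        stop("input file not found: ", if (is.null(p)) "(missing path)" else p,
             call. = FALSE)
      }
    }
  } else {
    stopifnot(inherits(simulate, "cohort_sim_config"))
  }
  structure(
    list(cells_csv = cells_csv, clinical_csv = clinical_csv,
         simulate = simulate, out_dir = out_dir, radius = radius,
         aggregation = aggregation, rules = rules, mw_mode = mw_mode,
         dichotomize_rule = dichotomize_rule,
         roc_arm = roc_arm, roc_histology = roc_histology),
    class = "run_config"
  )
}

#' Load a pipeline configuration from a YAML file
#'
#' Declarative counterpart of [run_config()]. Top-level keys are the
#' `run_config()` arguments (`cells_csv`, `clinical_csv`, `out_dir`,
#' `radius`, `aggregation`, `mw_mode`, `dichotomize_rule`, `roc_arm`,
#' `roc_histology`). A `simulate:` block switches to simulation mode with
#' keys `seed` (mandatory), `cores_per_patient`, `kappa_mpr` / `kappa_nmpr`
#' (two Beta shapes each), `core:` ([core_sim_config()] arguments, seed
#' ignored) and `groups:` (list of rows with arm, histology, n, p_mpr,
#' p_orr, p_pcr; defaults to [default_cohort_groups()]).
#'
#' @param path Path to a YAML file.
#' @return A [run_config()].
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  simulate <- NULL
  if (!is.null(y$simulate)) {
    s <- y$simulate
    tmpl <- do.call(core_sim_config, c(s$core, list(seed = 0L)))
    groups <- if (is.null(s$groups)) default_cohort_groups() else {
      dplyr::bind_rows(lapply(s$groups, function(row) {
        # YAML 1.1 reads a bare `n:` key as the boolean FALSE; undo that
        names(row)[names(row) %in% c("FALSE", "no")] <- "n"
        tibble::as_tibble(row)
      }))
    }
    simulate <- cohort_sim_config(
      groups = groups,
      cores_per_patient = s$cores_per_patient %||% 2,
      core_template = tmpl,
      kappa_mpr = unlist(s$kappa_mpr %||% c(2, 6)),
      kappa_nmpr = unlist(s$kappa_nmpr %||% c(6, 2)),
      seed = s$seed
    )
  }
  keep <- intersect(names(y), c("cells_csv", "clinical_csv", "out_dir",
                                "radius", "aggregation", "mw_mode",
                                "dichotomize_rule", "roc_arm",
                                "roc_histology"))
  do.call(run_config, c(y[keep], list(simulate = simulate)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes the whole chain on one configuration: load or simulate cell
#' tables and the clinical table; gate phenotypes; compute per-core and
#' per-patient spatial metrics; build response-rate tables (overall and per
#' arm); compare TME metrics between MPR and NMPR within the configured
#' subset; dichotomize each metric and fit univariate odds ratios against
#' MPR; run ROC analysis for each metric. Writes the bundle to `out_dir`:
#'
#' \itemize{
#'   \item `core_metrics.csv`, `patient_metrics.csv`
#'   \item `response_tables.csv` (per-outcome counts and dispatched p)
#'   \item `tme_comparison.csv` (median (Q1, Q3) summaries and MW p)
#'   \item `or_table.csv` (dichotomized univariate odds ratios)
#'   \item `roc_points.csv`, `roc_summary.csv`
#'   \item `manifest.json` (package version, config hash, warnings,
#'     exclusions, per-analysis status)
#' }
#'
#' The run is a pure function of (inputs, config): repeated runs produce
#' byte-identical numeric outputs. Statistical impossibilities (e.g. an empty
#' comparison group) are reported in the manifest without aborting the rest.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with every table in the bundle.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character()
  note <- function(...) {
    warnings_log <<- c(warnings_log, paste0(...))
  }

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- simulate_cohort(config$simulate)
    clinical <- sim$clinical
    tables <- sim$tables
  } else {
    tables <- parse_cell_table(config$cells_csv)
    clinical <- readr::read_csv(config$clinical_csv, show_col_types = FALSE,
                                progress = FALSE)
  }
  for (v in c("patient_id", "arm", "histology", "MPR", "ORR", "pCR")) {
    if (!v %in% names(clinical)) {
      stop("clinical table is missing column: ", v, call. = FALSE)
    }
  }

  # cells without clinical rows are excluded, with a manifest entry
  cell_pids <- unique(vapply(tables, function(tt) tt$patient_id, character(1)))
  orphans <- setdiff(cell_pids, clinical$patient_id)
  if (length(orphans)) {
    note("excluded ", length(orphans),
         " patient(s) absent from the clinical table: ",
         paste(orphans, collapse = ", "))
    warning("cell tables for patient(s) not in the clinical table: ",
            paste(orphans, collapse = ", "), call. = FALSE)
    tables <- Filter(function(tt) !(tt$patient_id %in% orphans), tables)
  }

  # --- phenotyping + spatial metrics -------------------------------------
  tables <- lapply(tables, assign_phenotypes, rules = config$rules)
  per_core <- dplyr::bind_rows(lapply(tables, core_metrics,
                                      radius = config$radius))
  per_patient <- cohort_metrics(tables, radius = config$radius,
                                aggregation = config$aggregation)
  merged <- dplyr::inner_join(clinical, per_patient, by = "patient_id")

  # --- response tables ----------------------------------------------------
  outcomes <- c("MPR", "ORR", "pCR")
  resp <- list(
    dplyr::mutate(response_table(clinical, outcomes, "histology"),
                  subset = "all", .before = 1)
  )
  for (arm in unique(clinical$arm)) {
    tab <- tryCatch(
      dplyr::mutate(response_table(clinical, outcomes, "histology",
                                   filter = list(arm = arm)),
                    subset = arm, .before = 1),
      error = function(e) {
        note("response table skipped for arm ", arm, ": ", conditionMessage(e))
        NULL
      }
    )
    resp[[length(resp) + 1L]] <- tab
  }
  response_tables <- dplyr::bind_rows(resp)

  # --- TME metric comparison (MPR vs NMPR in the configured subset) -------
  metric_vars <- c("density_PDL1", "density_PD1", "density_CAF",
                   "density_TAEC", "mean_nnd_um", "proximity_raw",
                   "proximity_per1000")
  sub <- merged[merged$arm == config$roc_arm &
                merged$histology == config$roc_histology, , drop = FALSE]
  sub$response <- factor(ifelse(sub$MPR, "MPR", "NMPR"),
                         levels = c("MPR", "NMPR"))
  tme_comparison <- NULL
  if (length(unique(sub$response[!is.na(sub$response)])) == 2L) {
    tme_comparison <- compare_groups(sub, metric_vars, "response",
                                     mode = config$mw_mode)
  } else {
    note("TME comparison skipped: need both MPR and NMPR patients in ",
         config$roc_arm, "/", config$roc_histology)
  }

  # --- univariate odds ratios --------------------------------------------
  or_rows <- lapply(metric_vars, function(vv) {
    tryCatch({
      v <- sub[[vv]]
      ok <- !is.na(v)
      lab <- dichotomize(v[ok], rule = config$dichotomize_rule)
      res <- univariate_or(lab, sub$MPR[ok])
      dplyr::mutate(res, variable = vv, cut = attr(lab, "cut"), .before = 1)
    }, error = function(e) {
      note("odds ratio skipped for ", vv, ": ", conditionMessage(e))
      NULL
    })
  })
  or_table <- dplyr::bind_rows(or_rows)

  # --- ROC ----------------------------------------------------------------
  roc_points <- list(); roc_summary <- list()
  if (length(unique(sub$MPR)) == 2L) {
    for (vv in c("mean_nnd_um", "proximity_raw", "proximity_per1000")) {
      v <- sub[[vv]]
      ok <- !is.na(v)
      if (length(unique(sub$MPR[ok])) != 2L) {
        note("ROC skipped for ", vv, ": one class absent after NA removal")
        next
      }
      rr <- roc_curve(v[ok], sub$MPR[ok], positive = TRUE)
      roc_points[[vv]] <- dplyr::mutate(rr$points, variable = vv, .before = 1)
      roc_summary[[vv]] <- tibble::tibble(
        variable = vv, auc = rr$auc, threshold = rr$threshold,
        sensitivity = rr$sensitivity, specificity = rr$specificity,
        flipped = rr$flipped, n_pos = rr$n_pos, n_neg = rr$n_neg
      )
    }
  } else {
    note("ROC skipped: one response class absent in ",
         config$roc_arm, "/", config$roc_histology)
  }
  roc_points <- dplyr::bind_rows(roc_points)
  roc_summary <- dplyr::bind_rows(roc_summary)

  # --- write bundle -------------------------------------------------------
  out <- list(core_metrics = per_core, patient_metrics = merged,
              response_tables = response_tables,
              tme_comparison = tme_comparison, or_table = or_table,
              roc_points = roc_points, roc_summary = roc_summary)
  for (nm in names(out)) {
    if (!is.null(out[[nm]]) && nrow(out[[nm]])) {
      readr::write_csv(out[[nm]], file.path(config$out_dir,
                                            paste0(nm, ".csv")))
    }
  }
  manifest <- list(
    package = "tmespatial",
    version = as.character(utils::packageVersion("tmespatial")),
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    radius_um = config$radius,
    aggregation = config$aggregation,
    n_patients = nrow(clinical),
    n_cores = length(tables),
    excluded_patients = as.list(orphans),
    warnings = as.list(warnings_log)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}
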