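#' Configuration for a simulated TMA core
#'
#' Describes one synthetic tissue-microarray core: its size, total cell
#' count, the phenotype mix, the spatial pattern of the endothelial (TAEC)
#' cells, and the spatial coupling of fibroblasts (CAFs) to them.
#'
#' The generative model:
#' \itemize{
#'   \item cell counts per identity are multinomial at the configured
#'     fractions (CAF, TAEC, tumor = CK+, remainder "other");
#'   \item TAECs are either complete spatial randomness (`"poisson"`) or a
#'     vessel-like Thomas cluster process (`"cluster"`: uniform parents, cells
#'     scattered around a random parent with isotropic Gaussian sd
#'     `cluster_sd`);
#'   \item a fraction `kappa` of CAFs is coupled: each picks a uniformly
#'     chosen TAEC and is displaced from it by an isotropic Gaussian offset
#'     with scale `sigma_couple`; the remaining CAFs (and tumor/other cells)
#'     are uniform. Out-of-bounds draws are rejected and resampled;
#'   \item marker flags follow the assigned identity (CAF: aSMA+, TAEC:
#'     CD31+, tumor: CK+), PD-L1/PD-1 positivity is independent Bernoulli at
#'     the configured rates, and every marker is flipped independently with
#'     probability `marker_flip` to emulate gating noise.
#' }
#'
#' Defaults emulate a 1 x 1 mm core of 2000 cells with CAF/TAEC fractions in
#' the range reported for neoadjuvant NSCLC biopsies (CAF density ~450/1000,
#' TAEC ~150/1000) and 60 vessel-profile clusters per square millimetre, a
#' microvessel density typical of NSCLC. With `sigma_couple = 15` um, sweeping
#' `kappa` from 0 to 1 moves the mean CAF->TAEC nearest-neighbor distance
#' from roughly 50 down to 13 um, spanning the observed 17-35 um range.
#'
#' @param width,height Core bounds in micrometres.
#' @param n_cells Total cell count.
#' @param frac_caf,frac_taec,frac_tumor Identity fractions (sum <= 1).
#' @param taec_pattern `"poisson"` or `"cluster"`.
#' @param n_parents,cluster_sd Thomas-process parameters for `"cluster"`.
#' @param kappa Coupled CAF fraction in `[0, 1]`.
#' @param sigma_couple Gaussian coupling scale in micrometres (> 0).
#' @param pdl1_rate,pd1_rate Bernoulli positivity rates for PD-L1 / PD-1.
#' @param marker_flip Per-marker flip probability.
#' @param seed Mandatory integer seed.
#' @return Object of class `core_sim_config`.
#' @export
core_sim_config <- function(width = 1000, height = 1000, n_cells = 2000,
                            frac_caf = 0.45, frac_taec = 0.15,
                            frac_tumor = 0.30,
                            taec_pattern = c("cluster", "poisson"),
                            n_parents = 60, cluster_sd = 20,
                            kappa = 0.3, sigma_couple = 15,
                            pdl1_rate = 0.05, pd1_rate = 0.02,
                            marker_flip = 0, seed) {
  taec_pattern <- match.arg(taec_pattern)
  if (missing(seed) || is.null(seed)) {
    stop("seed is mandatory for a reproducible core simulation", call. = FALSE)
  }
  fr <- c(frac_caf, frac_taec, frac_tumor)
  if (any(fr < 0) || sum(fr) > 1) {
    stop("identity fractions must be non-negative and sum to at most 1",
         call. = FALSE)
  }
  stopifnot(kappa >= 0, kappa <= 1, sigma_couple > 0,
            width > 0, height > 0, n_cells >= 0,
            marker_flip >= 0, marker_flip <= 1)
  structure(
    list(width = width, height = height, n_cells = n_cells,
         frac_caf = frac_caf, frac_taec = frac_taec, frac_tumor = frac_tumor,
         taec_pattern = taec_pattern, n_parents = n_parents,
         cluster_sd = cluster_sd, kappa = kappa, sigma_couple = sigma_couple,
         pdl1_rate = pdl1_rate, pd1_rate = pd1_rate,
         marker_flip = marker_flip, seed = as.integer(seed)),
    class = "core_sim_config"
  )
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# resample out-of-bounds points by redrawing from `draw(k)`; after `max_iter`
# sweeps any stragglers fall back to uniform placement
resample_into_bounds <- function(pts, draw, width, height, max_iter = 100L) {
  it <- 0L
  repeat {
    bad <- which(pts[, 1] < 0 | pts[, 1] > width |
                 pts[, 2] < 0 | pts[, 2] > height)
    if (!length(bad)) return(pts)
    it <- it + 1L
    if (it > max_iter) {
      pts[bad, 1] <- stats::runif(length(bad), 0, width)
      pts[bad, 2] <- stats::runif(length(bad), 0, height)
      return(pts)
    }
    pts[bad, ] <- draw(length(bad))
  }
}

#' Simulate one TMA core
#'
#' Draws a [cell_table()] from a [core_sim_config()]. Reproducible: the same
#' config (including seed) yields an identical table. The true simulated
#' identity is kept in the `sim_identity` column; the marker columns are what
#' the analysis pipeline sees.
#'
#' @param config A [core_sim_config()].
#' @return A [cell_table()] (phenotypes not yet assigned).
#' @export
simulate_core <- function(config) {
  stopifnot(inherits(config, "core_sim_config"))
  with_seed(config$seed, {
    n <- config$n_cells
    probs <- c(CAF = config$frac_caf, TAEC = config$frac_taec,
               tumor = config$frac_tumor)
    probs <- c(probs, other = 1 - sum(probs))
    counts <- as.vector(stats::rmultinom(1, n, probs))
    names(counts) <- names(probs)
    w <- config$width; h <- config$height

    unif <- function(k) cbind(stats::runif(k, 0, w), stats::runif(k, 0, h))

    # TAECs
    n_taec <- counts[["TAEC"]]
    if (n_taec > 0 && config$taec_pattern == "cluster") {
      parents <- unif(max(1L, config$n_parents))
      draw_taec <- function(k) {
        pid <- sample.int(nrow(parents), k, replace = TRUE)
        parents[pid, , drop = FALSE] +
          matrix(stats::rnorm(2 * k, 0, config$cluster_sd), ncol = 2)
      }
      taec <- resample_into_bounds(draw_taec(n_taec), draw_taec, w, h)
    } else {
      taec <- unif(n_taec)
    }

    # CAFs: coupled fraction displaced from a random TAEC
    n_caf <- counts[["CAF"]]
    caf <- unif(n_caf)
    if (n_caf > 0 && n_taec > 0 && config$kappa > 0) {
      coupled <- stats::runif(n_caf) < config$kappa
      k <- sum(coupled)
      if (k > 0) {
        draw_caf <- function(m) {
          tid <- sample.int(n_taec, m, replace = TRUE)
          taec[tid, , drop = FALSE] +
            matrix(stats::rnorm(2 * m, 0, config$sigma_couple), ncol = 2)
        }
        caf[coupled, ] <- resample_into_bounds(draw_caf(k), draw_caf, w, h)
      }
    }

    tumor <- unif(counts[["tumor"]])
    other <- unif(counts[["other"]])

    # identity vector and coordinates share the caf/taec/tumor/other block order
    identity <- rep(names(counts), counts)
    xy <- rbind(caf, taec, tumor, other)

    mk <- function(on) as.integer(identity == on)
    cells <- tibble::tibble(
      cell_id = sprintf("c%05d", seq_len(n)),
      x = if (n) xy[, 1] else numeric(0),
      y = if (n) xy[, 2] else numeric(0),
      CK = mk("tumor"),
      aSMA = mk("CAF"),
      CD31 = mk("TAEC"),
      PDL1 = as.integer(stats::runif(n) < config$pdl1_rate),
      PD1 = as.integer(stats::runif(n) < config$pd1_rate),
      sim_identity = identity
    )
    if (config$marker_flip > 0) {
      for (m in c("CK", "aSMA", "CD31", "PDL1", "PD1")) {
        flip <- stats::runif(n) < config$marker_flip
        cells[[m]] <- ifelse(flip, 1L - cells[[m]], cells[[m]])
      }
    }
    cell_table("simpat", "simcore", cells, width = w, height = h)
  })
}

#' Default cohort scaffold
#'
#' Group sizes and response rates of a 104-patient neoadjuvant NSCLC cohort:
#' two regimens (chemoimmunotherapy NAIC, chemotherapy NAC) crossed with two
#' histologies (squamous SCC, adenocarcinoma ADC), with per-group MPR / ORR /
#' pCR rates matching the observed response tables.
#'
#' @return Tibble with columns arm, histology, n, p_mpr, p_orr, p_pcr.
#' @export
default_cohort_groups <- function() {
  tibble::tribble(
    ~arm,   ~histology, ~n, ~p_mpr, ~p_orr, ~p_pcr,
    "NAIC", "SCC",      22, 16/22,  13/22,  9/22,
    "NAIC", "ADC",      13,  4/13,   6/13,  2/13,
    "NAC",  "SCC",      24,  7/24,  10/24,  1/24,
    "NAC",  "ADC",      45,  9/45,  16/45,  1/45
  )
}

#' Configuration for a simulated cohort
#'
#' Wraps the per-core simulation in a patient cohort: group sizes and
#' response rates, cores per patient, and per-response-group distributions of
#' the CAF-TAEC coupling strength kappa. MPR patients draw kappa from
#' `Beta(kappa_mpr[1], kappa_mpr[2])` and NMPR patients from the `kappa_nmpr`
#' Beta; the defaults (mean 0.25 vs 0.75) put the MPR group at weaker
#' coupling, i.e. larger CAF->TAEC distances, matching the observed effect
#' direction.
#'
#' @param groups Tibble like [default_cohort_groups()].
#' @param cores_per_patient Cores simulated per patient.
#' @param core_template A [core_sim_config()] whose seed is ignored; per-core
#'   seeds are derived from `seed` by a counter scheme
#'   (`(seed + 7919 * core_index) mod (2^31 - 1)`).
#' @param kappa_mpr,kappa_nmpr Beta shape pairs for the coupling strength.
#' @param seed Master seed (mandatory).
#' @return Object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(groups = default_cohort_groups(),
                              cores_per_patient = 2,
                              core_template = core_sim_config(seed = 0L),
                              kappa_mpr = c(2, 6), kappa_nmpr = c(6, 2),
                              seed) {
  if (missing(seed) || is.null(seed)) {
    stop("seed is mandatory for a reproducible cohort simulation", call. = FALSE)
  }
  groups <- tibble::as_tibble(groups)
  req <- c("arm", "histology", "n", "p_mpr", "p_orr", "p_pcr")
  miss <- setdiff(req, names(groups))
  if (length(miss)) stop("groups is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(groups$n < 1)) stop("every cohort group needs n >= 1", call. = FALSE)
  rates <- as.matrix(groups[, c("p_mpr", "p_orr", "p_pcr")])
  if (any(rates < 0) || any(rates > 1)) {
    stop("response rates must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(all(kappa_mpr > 0), all(kappa_nmpr > 0),
            length(kappa_mpr) == 2L, length(kappa_nmpr) == 2L,
            cores_per_patient >= 1)
  structure(
    list(groups = groups, cores_per_patient = as.integer(cores_per_patient),
         core_template = core_template,
         kappa_mpr = kappa_mpr, kappa_nmpr = kappa_nmpr,
         seed = as.integer(seed)),
    class = "cohort_sim_config"
  )
}

derive_seed <- function(master, index) {
  as.integer((as.numeric(master) + 7919 * index) %% (2^31 - 1))
}

#' Simulate a patient cohort with per-group spatial coupling
#'
#' Draws patient labels per the configured rate table and one cell table per
#' core per patient. pCR is nested inside MPR (a single uniform draw per
#' patient: below the pCR rate gives pCR, below the MPR rate gives MPR),
#' respecting the pathology definitions; ORR is drawn independently. Each
#' patient's coupling strength kappa comes from the Beta distribution of
#' their response group, and all per-core seeds derive from the master seed
#' by a fixed counter scheme, so any core can be regenerated in isolation.
#'
#' @param config A [cohort_sim_config()].
#' @return List with `clinical` (tibble: patient_id, arm, histology, MPR,
#'   ORR, pCR, kappa) and `tables` (named list of phenotype-ready
#'   [cell_table()]s, `cores_per_patient` per patient).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  g <- config$groups
  clinical <- with_seed(config$seed, {
    rows <- lapply(seq_len(nrow(g)), function(i) {
      n <- g$n[i]
      u <- stats::runif(n)
      mpr <- u < g$p_mpr[i]
      pcr <- u < min(g$p_pcr[i], g$p_mpr[i])
      orr <- stats::runif(n) < g$p_orr[i]
      tibble::tibble(arm = g$arm[i], histology = g$histology[i],
                     MPR = mpr, ORR = orr, pCR = pcr)
    })
    cl <- dplyr::bind_rows(rows)
    cl$patient_id <- sprintf("P%03d", seq_len(nrow(cl)))
    cl$kappa <- ifelse(
      cl$MPR,
      stats::rbeta(nrow(cl), config$kappa_mpr[1], config$kappa_mpr[2]),
      stats::rbeta(nrow(cl), config$kappa_nmpr[1], config$kappa_nmpr[2])
    )
    cl[, c("patient_id", "arm", "histology", "MPR", "ORR", "pCR", "kappa")]
  })
  tmpl <- config$core_template
  tables <- list()
  core_index <- 0L
  for (i in seq_len(nrow(clinical))) {
    for (j in seq_len(config$cores_per_patient)) {
      core_index <- core_index + 1L
      cfg <- tmpl
      cfg$kappa <- clinical$kappa[i]
      cfg$seed <- derive_seed(config$seed, core_index)
      tab <- simulate_core(cfg)
      tab$patient_id <- clinical$patient_id[i]
      tab$core_id <- sprintf("core%d", j)
      tables[[paste(tab$patient_id, tab$core_id, sep = "/")]] <- tab
    }
  }
  list(clinical = clinical, tables = tables)
}

#' Closed-form expectations for a homogeneous Poisson target pattern
#'
#' For target cells forming a homogeneous Poisson process of intensity
#' `lambda` (cells per square micrometre) and source cells placed
#' independently, the expected nearest-neighbor distance is `1 / (2
#' sqrt(lambda))` and the probability that a source cell has at least one
#' target within radius `r` is `1 - exp(-lambda pi r^2)`. Used as the
#' analytic oracle for the simulator and the spatial metrics (edge effects
#' make finite cores fall slightly short of the infinite-window values).
#'
#' @param lambda Target intensity per square micrometre (> 0).
#' @param r Radius in micrometres.
#' @return List with `expected_nnd` (um) and `expected_proximity_prob`.
#' @export
closed_form_checks <- function(lambda, r = 30) {
  stopifnot(lambda > 0, r >= 0)
  list(
    expected_nnd = 1 / (2 * sqrt(lambda)),
    expected_proximity_prob = 1 - exp(-lambda * pi * r^2)
  )
}
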