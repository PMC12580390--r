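# Fixtures are built in code: small cell tables with known geometry, plus
# brute-force statistical oracles kept independent of the package internals.

# cell table from explicit phenotype-bearing points; markers follow identity
make_table <- function(caf = NULL, taec = NULL, tumor = NULL, other = NULL,
                       width = NULL, height = NULL, patient = "P1",
                       core = "c1") {
  as_mat <- function(p) {
    if (is.null(p)) return(matrix(numeric(0), ncol = 2))
    if (is.null(dim(p))) p <- matrix(p, ncol = 2, byrow = TRUE)
    p
  }
  caf <- as_mat(caf); taec <- as_mat(taec)
  tumor <- as_mat(tumor); other <- as_mat(other)
  xy <- rbind(caf, taec, tumor, other)
  ident <- rep(c("CAF", "TAEC", "tumor", "other"),
               c(nrow(caf), nrow(taec), nrow(tumor), nrow(other)))
  cells <- tibble::tibble(
    cell_id = sprintf("f%03d", seq_len(nrow(xy))),
    x = xy[, 1], y = xy[, 2],
    CK = as.integer(ident == "tumor"),
    aSMA = as.integer(ident == "CAF"),
    CD31 = as.integer(ident == "TAEC"),
    PDL1 = 0L, PD1 = 0L
  )
  tab <- cell_table(patient, core, cells, width = width, height = height)
  assign_phenotypes(tab)
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mw_enum_oracle <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  u_of <- function(a, b) {
    r <- rank(c(a, b))
    sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  }
  u_obs <- u_of(x, y)
  sel <- utils::combn(length(pooled), n1)
  us <- apply(sel, 2, function(s) u_of(pooled[s], pooled[-s]))
  lo <- mean(us <= u_obs + 1e-9)
  hi <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# two-sided Fisher p by direct hypergeometric enumeration on a 2x2 table
fisher_enum_oracle <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  a_range <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(a_range, r1, n - r1, c1)
  p_obs <- stats::dhyper(m[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# clinical table whose histology x outcome cross-tabs equal given counts
clinical_from_counts <- function(arm, scc_yes, scc_no, adc_yes, adc_no,
                                 outcome = "MPR") {
  n <- scc_yes + scc_no + adc_yes + adc_no
  d <- tibble::tibble(
    patient_id = sprintf("%s%03d", arm, seq_len(n)),
    arm = arm,
    histology = rep(c("SCC", "ADC"), c(scc_yes + scc_no, adc_yes + adc_no))
  )
  d[[outcome]] <- rep(c(TRUE, FALSE, TRUE, FALSE),
                      c(scc_yes, scc_no, adc_yes, adc_no))
  d
}

# fixed scaffold of 7 responders / 4 non-responders (response forced by rate)
scaffold_groups <- function() {
  tibble::tibble(arm = "NAIC", histology = "SCC",
                 n = c(7, 4), p_mpr = c(1, 0), p_orr = 0.5, p_pcr = 0)
}

small_core_template <- function(n_cells = 300, ...) {
  core_sim_config(n_cells = n_cells, width = 600, height = 600, seed = 0L, ...)
}

# Monte-Carlo comparison of replicate means against a constant: the SE is
# empirical across replicates, which absorbs the within-replicate dependence
# of per-source statistics sharing one target realization
expect_within_3se <- function(per_rep, expected) {
  se <- stats::sd(per_rep) / sqrt(length(per_rep))
  expect_lt(abs(mean(per_rep) - expected), 3 * se)
}
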