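#' Build a contingency table from a clinical table
#'
#' Cross-tabulates two categorical patient-level variables into an r x c count
#' matrix, optionally after filtering (e.g. to one treatment arm). Level
#' order follows factor levels when set, otherwise order of first appearance
#' in the (unfiltered) data, so printed tables keep the input's layout.
#'
#' @param patients Data frame of patient-level variables.
#' @param row_var,col_var Column names of the two categorical variables.
#' @param filter Optional named list of equality conditions, e.g.
#'   `list(arm = "NAIC")`. An empty selection is an error naming the filter.
#' @return Integer matrix of counts with dimnames; class `contingency_table`.
#' @export
build_contingency <- function(patients, row_var, col_var, filter = NULL) {
  stopifnot(is.data.frame(patients))
  for (v in c(row_var, col_var)) {
    if (!v %in% names(patients)) stop("unknown variable: ", v, call. = FALSE)
  }
  lev <- function(v) {
    x <- patients[[v]]
    if (is.factor(x)) levels(x) else unique(as.character(x[!is.na(x)]))
  }
  rl <- lev(row_var); cl <- lev(col_var)
  keep <- rep(TRUE, nrow(patients))
  if (!is.null(filter)) {
    stopifnot(is.list(filter), !is.null(names(filter)))
    for (v in names(filter)) {
      if (!v %in% names(patients)) stop("unknown filter variable: ", v, call. = FALSE)
      keep <- keep & patients[[v]] %in% filter[[v]]
    }
    if (!any(keep)) {
      stop("filter matches no patients: ",
           paste(names(filter), unlist(filter), sep = "=", collapse = ", "),
           call. = FALSE)
    }
  }
  d <- patients[keep, , drop = FALSE]
  tab <- table(factor(as.character(d[[row_var]]), levels = rl),
               factor(as.character(d[[col_var]]), levels = cl))
  m <- matrix(as.integer(tab), nrow = length(rl),
              dimnames = list(rl, cl))
  structure(m, class = c("contingency_table", class(m)))
}

as_count_matrix <- function(table) {
  m <- unclass(table)
  if (!is.matrix(m) || !is.numeric(m) || any(m < 0) || any(m != round(m))) {
    stop("contingency table must be a matrix of non-negative counts",
         call. = FALSE)
  }
  m
}

test_result <- function(method, statistic = NA_real_, df = NA_real_, p,
                        note = NA_character_) {
  tibble::tibble(method = method, statistic = statistic, df = df,
                 p = p, note = note)
}

#' Chi-squared test of independence
#'
#' Pearson chi-squared test on an r x c count table. For 2 x 2 tables with
#' `correction = "auto"` (or `"on"`), the Yates continuity correction is
#' applied: each cell contributes `(max(0, |O - E| - 0.5))^2 / E`. The p-value
#' comes from the chi-squared survival function with `(r-1)(c-1)` degrees of
#' freedom. A zero row or column marginal leaves the test undefined and
#' errors.
#'
#' @param table A count matrix or [build_contingency()] result.
#' @param correction `"auto"` (Yates on 2 x 2 only, the default), `"on"`, or
#'   `"off"`.
#' @return One-row tibble: method (`pearson_chi2` or `yates_chi2`),
#'   statistic, df, two-sided p.
#' @export
chi2_test <- function(table, correction = c("auto", "on", "off")) {
  correction <- match.arg(correction)
  m <- as_count_matrix(table)
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need at least a 2 x 2 table", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero marginal: chi-squared test undefined", call. = FALSE)
  }
  is2x2 <- nrow(m) == 2L && ncol(m) == 2L
  correct <- switch(correction, auto = is2x2, on = is2x2, off = FALSE)
  res <- suppressWarnings(stats::chisq.test(m, correct = correct))
  test_result(
    method = if (correct) "yates_chi2" else "pearson_chi2",
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p = res$p.value
  )
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided exact test: the p-value sums the hypergeometric probabilities of
#' every table with the observed marginals whose point probability does not
#' exceed that of the observed table (with a 1e-7 relative tolerance on the
#' comparison, the standard convention).
#'
#' @param table A 2 x 2 count matrix.
#' @return One-row tibble with method `fisher_exact`, the conditional MLE
#'   odds ratio as the statistic, and the two-sided p.
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as_count_matrix(table)
  if (!(nrow(m) == 2L && ncol(m) == 2L)) stop("need a 2 x 2 table", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero marginal: Fisher test undefined", call. = FALSE)
  }
  res <- stats::fisher.test(m)
  test_result(method = "fisher_exact", statistic = unname(res$estimate),
              p = res$p.value)
}

#' Dispatch a 2 x 2 response-table test
#'
#' Convention used throughout the response tables: Yates-corrected
#' chi-squared unless any expected count is below 5, in which case Fisher's
#' exact test is used.
#'
#' @param table A 2 x 2 count matrix.
#' @return One-row tibble from [chi2_test()] or [fisher_exact_2x2()].
#' @export
dispatch_2x2_test <- function(table) {
  m <- as_count_matrix(table)
  if (!(nrow(m) == 2L && ncol(m) == 2L)) stop("need a 2 x 2 table", call. = FALSE)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) fisher_exact_2x2(m) else chi2_test(m, "auto")
}

mw_u_from_ranks <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

mw_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_obs <- mw_u_from_ranks(x, y)
  if (!anyDuplicated(pooled)) {
    # tie-free: U null distribution by the standard counting recursion
    # (stats::pwilcox implements it)
    u_int <- round(u_obs)
    lo <- stats::pwilcox(u_int, n1, n2)
    hi <- 1 - stats::pwilcox(u_int - 1L, n1, n2)
  } else {
    idx <- utils::combn(n1 + n2, n1)
    us <- apply(idx, 2L, function(sel) {
      mw_u_from_ranks(pooled[sel], pooled[-sel])
    })
    lo <- mean(us <= u_obs + 1e-9)
    hi <- mean(us >= u_obs - 1e-9)
  }
  min(1, 2 * min(lo, hi))
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The statistic is
#' `U = R1 - n1(n1+1)/2` from midranks. Modes:
#' \describe{
#'   \item{exact}{permutation-exact two-sided p. Without ties the U null
#'     distribution is built by the standard counting recursion; with ties
#'     the full set of `choose(n1+n2, n1)` group assignments of the pooled
#'     values is enumerated (supported for `n1 + n2 <= 12`).}
#'   \item{asymptotic}{normal approximation with the midrank tie correction,
#'     `z = (U - n1 n2 / 2) / sqrt(n1 n2 / 12 * ((N+1) - sum(t^3 - t) /
#'     (N (N-1))))`, two-sided, without continuity correction (the convention
#'     under which a 7-vs-4 comparison with U = 3 gives p = 0.038).}
#'   \item{auto}{exact when `n1 + n2 <= 12`, else asymptotic.}
#' }
#' Two identical constant samples are degenerate: p = 1 with a warning.
#'
#' @param x,y Numeric samples.
#' @param mode `"auto"`, `"exact"`, or `"asymptotic"`.
#' @return One-row tibble: method (`mw_exact` or `mw_asymptotic`), U
#'   statistic, two-sided p.
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  u <- mw_u_from_ranks(x, y)
  if (length(unique(pooled)) == 1L) {
    warning("all values identical across both samples; test is degenerate")
    return(test_result("mw_degenerate", statistic = u, p = 1,
                       note = "degenerate"))
  }
  has_ties <- anyDuplicated(pooled) > 0L
  if (mode == "auto") {
    mode <- if (N <= 12L) "exact" else "asymptotic"
  }
  if (mode == "exact" && has_ties && N > 12L) {
    warning("exact mode with ties supported only for n1 + n2 <= 12; ",
            "falling back to asymptotic")
    mode <- "asymptotic"
  }
  if (mode == "exact") {
    p <- mw_exact_p(x, y)
    return(test_result("mw_exact", statistic = u, p = p))
  }
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  v <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (v <= 0) {
    warning("zero variance under ties; test is degenerate")
    return(test_result("mw_degenerate", statistic = u, p = 1,
                       note = "degenerate"))
  }
  z <- (u - n1 * n2 / 2) / sqrt(v)
  test_result("mw_asymptotic", statistic = u, p = 2 * stats::pnorm(-abs(z)))
}

#' Median and quartiles
#'
#' Summary convention for continuous variables: median with first and third
#' quartiles. `"linear"` (default) is the linear-interpolation quantile
#' definition (type 7); `"haverage"` is the weighted average at `(n+1)p`
#' (type 6), the convention SPSS labels HAVERAGE.
#'
#' @param values Numeric vector (length >= 1; NAs dropped).
#' @param convention `"linear"` or `"haverage"`.
#' @return Named numeric vector `c(median, q1, q3)`.
#' @export
median_iqr <- function(values, convention = c("linear", "haverage")) {
  convention <- match.arg(convention)
  values <- values[!is.na(values)]
  stopifnot(length(values) >= 1L)
  type <- if (convention == "linear") 7 else 6
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), type = type, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Dichotomize a continuous predictor
#'
#' Splits values into `"low"` / `"high"` at a cut: the sample median (default
#' rule) or a fixed threshold. Values below the cut are low; values at or
#' above it are high (ties at the cut go to high). A median split over
#' all-equal values is impossible and errors.
#'
#' @param values Numeric vector.
#' @param rule `"median"` or a single numeric threshold.
#' @return Factor with levels `c("low", "high")` and the cut in attribute
#'   `"cut"`.
#' @export
dichotomize <- function(values, rule = "median") {
  stopifnot(is.numeric(values))
  if (identical(rule, "median")) {
    stopifnot(length(values[!is.na(values)]) >= 2L)
    cut <- stats::median(values, na.rm = TRUE)
    if (all(values[!is.na(values)] == cut)) {
      stop("all values equal; median split impossible", call. = FALSE)
    }
  } else {
    stopifnot(is.numeric(rule), length(rule) == 1L)
    cut <- rule
  }
  f <- factor(ifelse(values < cut, "low", "high"), levels = c("low", "high"))
  attr(f, "cut") <- cut
  f
}

#' Univariate odds ratio for a binary predictor
#'
#' Cross-tabulates a two-level predictor against a binary outcome and reports
#' the cross-product odds ratio `OR = (a d) / (b c)`, where `a` counts events
#' in the first predictor level and `d` non-events in the second. The 95% CI
#' is Wald: `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`; p is from the
#' Wald z. With any zero cell the Haldane-Anscombe correction (+0.5 to every
#' cell) is applied and flagged.
#'
#' @param predictor Factor or vector with exactly two levels; the reported OR
#'   is for the first level relative to the second.
#' @param outcome Logical vector (or 0/1), `TRUE` = event.
#' @param conf_level Confidence level of the Wald interval.
#' @return One-row tibble: or, ci_lower, ci_upper, p, corrected (logical),
#'   split (level comparison as a string).
#' @export
univariate_or <- function(predictor, outcome, conf_level = 0.95) {
  predictor <- as.factor(predictor)
  if (nlevels(droplevels(predictor)) != 2L) {
    stop("predictor must have exactly two observed levels", call. = FALSE)
  }
  predictor <- droplevels(predictor)
  outcome <- as.logical(outcome)
  stopifnot(length(predictor) == length(outcome), !anyNA(outcome))
  if (length(unique(outcome)) == 1L) {
    stop("outcome is constant; odds ratio undefined", call. = FALSE)
  }
  lv <- levels(predictor)
  a <- sum(predictor == lv[1] & outcome)
  b <- sum(predictor == lv[1] & !outcome)
  c_ <- sum(predictor == lv[2] & outcome)
  d <- sum(predictor == lv[2] & !outcome)
  or_from_2x2(a, b, c_, d, conf_level = conf_level,
              split = paste(lv[1], "vs", lv[2]))
}

#' @rdname univariate_or
#' @param a,b,c_,d Cell counts: predictor level 1 events / non-events,
#'   level 2 events / non-events.
#' @param split Label describing the comparison.
#' @export
or_from_2x2 <- function(a, b, c_, d, conf_level = 0.95, split = "level1 vs level2") {
  cells <- c(a, b, c_, d)
  stopifnot(all(cells >= 0))
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  a <- cells[1]; b <- cells[2]; cc <- cells[3]; dd <- cells[4]
  or <- (a * dd) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / dd)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  z <- log(or) / se
  tibble::tibble(
    or = or,
    ci_lower = exp(log(or) - zq * se),
    ci_upper = exp(log(or) + zq * se),
    p = 2 * stats::pnorm(-abs(z)),
    corrected = corrected,
    split = split
  )
}

#' Empirical ROC curve with Youden-optimal operating point
#'
#' Builds the empirical ROC over all distinct score thresholds (predict
#' positive when `score >= threshold`) and reports:
#' \itemize{
#'   \item AUC by the trapezoidal rule, internally cross-checked against the
#'     concordance identity `AUC = (concordant + 0.5 tied) / (n+ n-)`;
#'   \item the Youden-optimal threshold (maximizes sensitivity + specificity
#'     - 1; ties broken in favor of higher specificity) with its sensitivity
#'     and specificity;
#'   \item the orientation: when the raw AUC is below 0.5 the score is negated
#'     so that higher always predicts positive, and the flip is recorded.
#' }
#'
#' @param scores Numeric scores.
#' @param labels Class labels; `positive` names the positive class.
#' @param positive Value of `labels` treated as positive (default `TRUE`).
#' @return Object of class `roc_result`: list with `points` (tibble of
#'   threshold, sensitivity, specificity), `auc`, `threshold`, `sensitivity`,
#'   `specificity`, `flipped`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels, positive = TRUE) {
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present for a ROC curve", call. = FALSE)
  }
  flipped <- FALSE
  if (roc_auc_trapezoid(scores, pos) < 0.5) {
    scores <- -scores
    flipped <- TRUE
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) sum(pos & scores >= t) / n_pos, numeric(1))
  spec <- vapply(thr, function(t) sum(!pos & scores < t) / n_neg, numeric(1))
  points <- tibble::tibble(
    threshold = c(Inf, thr),
    sensitivity = c(0, sens),
    specificity = c(1, spec)
  )
  auc <- roc_auc_trapezoid(scores, pos)
  # concordance cross-check: trapezoidal AUC must equal the U-statistic form
  auc_u <- roc_auc_concordance(scores, pos)
  if (abs(auc - auc_u) > 1e-9) {
    stop("internal inconsistency: trapezoidal AUC ", auc,
         " != concordance AUC ", auc_u, call. = FALSE)
  }
  youden <- points$sensitivity + points$specificity - 1
  best <- which(youden == max(youden))
  if (length(best) > 1L) best <- best[which.max(points$specificity[best])]
  structure(
    list(points = points, auc = auc,
         threshold = points$threshold[best],
         sensitivity = points$sensitivity[best],
         specificity = points$specificity[best],
         flipped = flipped, n_pos = n_pos, n_neg = n_neg),
    class = "roc_result"
  )
}

roc_auc_trapezoid <- function(scores, pos) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  tpr <- c(0, vapply(thr, function(t) sum(pos & scores >= t) / n_pos, numeric(1)))
  fpr <- c(0, vapply(thr, function(t) sum(!pos & scores >= t) / n_neg, numeric(1)))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

roc_auc_concordance <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  conc <- 0; tied <- 0
  for (v in sp) {
    conc <- conc + sum(v > sn)
    tied <- tied + sum(v == sn)
  }
  (conc + 0.5 * tied) / (length(sp) * length(sn))
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC = ", format(x$auc, digits = 4),
      " (", x$n_pos, " positive, ", x$n_neg, " negative",
      if (x$flipped) "; orientation flipped" else "", ")\n",
      "  Youden-optimal threshold ", format(x$threshold, digits = 4),
      ": sensitivity ", format(x$sensitivity, digits = 4),
      ", specificity ", format(x$specificity, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Group comparison of continuous TME metrics
#'
#' Mirrors the cohort's comparison-table layout: for each metric, the two
#' groups' `median (Q1, Q3)` summaries and a two-sided Mann-Whitney p.
#'
#' @param data Data frame holding metrics and a grouping column.
#' @param value_vars Character vector of metric column names.
#' @param group_var Name of the two-level grouping column.
#' @param mode Mann-Whitney mode passed to [mann_whitney()].
#' @param convention Quartile convention passed to [median_iqr()].
#' @return Tibble: variable, one summary column per group, n per group,
#'   method, p.
#' @export
compare_groups <- function(data, value_vars, group_var, mode = "auto",
                           convention = "linear") {
  g <- as.factor(data[[group_var]])
  g <- droplevels(g)
  if (nlevels(g) != 2L) stop("group variable must have two observed levels",
                             call. = FALSE)
  lv <- levels(g)
  fmt <- function(v) {
    s <- median_iqr(v, convention)
    sprintf("%.1f (%.1f, %.1f)", s["median"], s["q1"], s["q3"])
  }
  rows <- lapply(value_vars, function(vv) {
    x <- data[[vv]][g == lv[1]]
    y <- data[[vv]][g == lv[2]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) == 0L || length(y) == 0L) {
      return(tibble::tibble(variable = vv,
                            g1 = NA_character_, g2 = NA_character_,
                            n1 = length(x), n2 = length(y),
                            method = NA_character_, p = NA_real_))
    }
    res <- mann_whitney(x, y, mode = mode)
    tibble::tibble(variable = vv, g1 = fmt(x), g2 = fmt(y),
                   n1 = length(x), n2 = length(y),
                   method = res$method, p = res$p)
  })
  out <- dplyr::bind_rows(rows)
  names(out)[names(out) == "g1"] <- lv[1]
  names(out)[names(out) == "g2"] <- lv[2]
  out
}

#' Response-rate table with dispatched tests
#'
#' Builds the response-table layout: for each binary outcome, the per-group
#' yes/no counts (with percentages) and the p-value from [dispatch_2x2_test()]
#' (Yates chi-squared, or Fisher when any expected count is below 5).
#'
#' @param patients Clinical table with logical outcome columns.
#' @param outcome_vars Character vector of logical outcome column names.
#' @param group_var Name of the two-level grouping column (e.g. histology).
#' @param filter Optional filter passed to [build_contingency()].
#' @return Tibble: outcome, per-group "n (pct)" strings for yes/no, method, p.
#' @export
response_table <- function(patients, outcome_vars, group_var, filter = NULL) {
  rows <- lapply(outcome_vars, function(ov) {
    d <- patients
    d[[ov]] <- factor(ifelse(as.logical(d[[ov]]), "Yes", "No"),
                      levels = c("Yes", "No"))
    tab <- build_contingency(d, ov, group_var, filter = filter)
    # a degenerate table (one group level, outcome constant) is reported,
    # not fatal: the row keeps its counts with an NA p
    res <- tryCatch(dispatch_2x2_test(tab), error = function(e) {
      test_result(NA_character_, p = NA_real_, note = conditionMessage(e))
    })
    if (ncol(tab) < 2L) {
      tab <- cbind(tab, "(absent)" = 0L)
    }
    tot <- colSums(tab)
    pct <- sweep(tab, 2L, pmax(tot, 1L), "/") * 100
    tibble::tibble(
      outcome = ov,
      level = rownames(tab),
      !!colnames(tab)[1] := sprintf("%d (%.1f%%)", tab[, 1], pct[, 1]),
      !!colnames(tab)[2] := sprintf("%d (%.1f%%)", tab[, 2], pct[, 2]),
      method = res$method,
      p = res$p
    )
  })
  dplyr::bind_rows(rows)
}
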