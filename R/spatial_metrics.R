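#' Nearest-neighbor distances from each source point to a target set
#'
#' For every source point, the Euclidean distance (micrometres) to the closest
#' target point. Source and target sets may share coordinates, so a distance
#' of 0 is legitimate. The default `"grid"` method buckets targets on a
#' uniform grid and searches outward ring by ring, stopping once no unvisited
#' ring can hold a closer point; it returns exactly the same distances as the
#' all-pairs `"brute"` method, which is retained as an independent oracle.
#'
#' @param source,target Two-column matrices or data frames of x/y coordinates.
#' @param method `"grid"` (bucketed search) or `"brute"` (all pairs).
#' @return Numeric vector, one distance per source row.
#' @examples
#' nearest_neighbor_distances(cbind(0, 0), cbind(c(3, 10), c(4, 0)))  # 5
#' @export
nearest_neighbor_distances <- function(source, target,
                                       method = c("grid", "brute")) {
  method <- match.arg(method)
  source <- as_xy(source)
  target <- as_xy(target)
  if (nrow(target) == 0L) {
    stop("target point set is empty: nearest-neighbor distance undefined",
         call. = FALSE)
  }
  if (nrow(source) == 0L) return(numeric(0))
  if (method == "brute") nn_brute(source, target) else nn_grid(source, target)
}

as_xy <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p[, 1:2])
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  storage.mode(p) <- "double"
  if (ncol(p) != 2L || any(!is.finite(p))) {
    stop("point sets must be finite n x 2 coordinates", call. = FALSE)
  }
  p
}

nn_brute <- function(source, target) {
  # all-pairs minima; chunked over sources to bound memory
  ns <- nrow(source)
  out <- numeric(ns)
  chunk <- max(1L, floor(4e6 / nrow(target)))
  for (i0 in seq(1L, ns, by = chunk)) {
    idx <- i0:min(ns, i0 + chunk - 1L)
    dx <- outer(source[idx, 1], target[, 1], "-")
    dy <- outer(source[idx, 2], target[, 2], "-")
    d2 <- dx * dx + dy * dy
    out[idx] <- sqrt(apply(d2, 1L, min))
  }
  out
}

nn_grid <- function(source, target) {
  nt <- nrow(target)
  xr <- range(c(source[, 1], target[, 1]))
  yr <- range(c(source[, 2], target[, 2]))
  span <- max(xr[2] - xr[1], yr[2] - yr[1])
  if (span <= 0) {
    # all points coincide in at least one frame; brute is exact and trivial
    return(nn_brute(source, target))
  }
  h <- span / max(1, floor(sqrt(nt)))
  gx_t <- as.integer(floor((target[, 1] - xr[1]) / h))
  gy_t <- as.integer(floor((target[, 2] - yr[1]) / h))
  gxm <- max(gx_t); gym <- max(gy_t)
  ncx <- gxm + 1L
  buckets <- split(seq_len(nt), gx_t + gy_t * ncx)
  gx_s <- as.integer(floor((source[, 1] - xr[1]) / h))
  gy_s <- as.integer(floor((source[, 2] - yr[1]) / h))
  # every target bucket is within this many rings of any source cell
  max_ring <- max(gxm, max(gx_s)) + max(gym, max(gy_s)) + 2L
  out <- numeric(nrow(source))
  for (i in seq_len(nrow(source))) {
    cx <- gx_s[i]; cy <- gy_s[i]
    best <- Inf
    k <- 0L
    repeat {
      # cells at Chebyshev distance k from (cx, cy)
      if (k == 0L) {
        cells <- cbind(cx, cy)
      } else {
        xs <- (cx - k):(cx + k)
        ys <- (cy - k + 1L):(cy + k - 1L)
        cells <- rbind(
          cbind(xs, cy - k), cbind(xs, cy + k),
          cbind(cx - k, ys), cbind(cx + k, ys)
        )
      }
      # clip to the occupied grid so keys cannot alias across rows
      keep <- cells[, 1] >= 0L & cells[, 1] <= gxm &
              cells[, 2] >= 0L & cells[, 2] <= gym
      cells <- cells[keep, , drop = FALSE]
      if (nrow(cells)) {
        keys <- as.character(cells[, 1] + cells[, 2] * ncx)
        cand <- unlist(buckets[keys], use.names = FALSE)
        if (length(cand)) {
          dx <- target[cand, 1] - source[i, 1]
          dy <- target[cand, 2] - source[i, 2]
          best <- min(best, min(dx * dx + dy * dy))
        }
      }
      # any point in ring k+1 or beyond lies at squared distance >= (k*h)^2
      if (best <= (k * h)^2 || k > max_ring) break
      k <- k + 1L
    }
    out[i] <- sqrt(best)
  }
  out
}

xy_of <- function(table, phenotype) {
  d <- table$cells
  if (!"phenotype" %in% names(d)) {
    stop("table has no phenotype column; run assign_phenotypes() first",
         call. = FALSE)
  }
  sel <- d$phenotype == phenotype
  cbind(d$x[sel], d$y[sel])
}

undefined_metric <- function(reason) {
  structure(NA_real_, reason = reason)
}

#' Phenotype density per 1000 cells
#'
#' Density is the count of cells of a phenotype (or of cells positive for a
#' marker, used for PD-L1/PD-1 "expression") per 1000 total nucleated cells in
#' the core: `1000 * count / n_cells`. An empty core yields `NA` (the metric
#' is undefined, not zero).
#'
#' @param table A phenotyped [cell_table()].
#' @param phenotype Phenotype label, or `NULL` when `marker` is given.
#' @param marker Marker name whose positive fraction is wanted, or `NULL`.
#' @return Cells per 1000 cells (0..1000), or `NA` for an empty core.
#' @export
density_per_1000 <- function(table, phenotype = NULL, marker = NULL) {
  stopifnot(inherits(table, "cell_table"))
  n <- nrow(table$cells)
  if (n == 0L) return(undefined_metric("empty_core"))
  1000 * count_cells(table, phenotype = phenotype, marker = marker) / n
}

#' Mean nearest-neighbor distance between two phenotypes
#'
#' Arithmetic mean over all source-phenotype cells of the distance to the
#' nearest target-phenotype cell, in micrometres (for CAF -> TAEC: the mean
#' distance from each aSMA+/CK- cell to its closest CD31+/CK- cell). When the
#' core has no source or no target cells the metric is undefined and `NA` is
#' returned with a `reason` attribute (`"no_source"` or `"no_target"`).
#'
#' No edge correction is applied: cells near the core boundary keep their
#' observed nearest neighbor.
#'
#' @param table A phenotyped [cell_table()].
#' @param source_phenotype,target_phenotype Phenotype labels.
#' @param method Passed to [nearest_neighbor_distances()].
#' @return Mean distance in micrometres, or `NA` with a `reason` attribute.
#' @export
mean_nnd <- function(table, source_phenotype = "CAF", target_phenotype = "TAEC",
                     method = "grid") {
  src <- xy_of(table, source_phenotype)
  tgt <- xy_of(table, target_phenotype)
  if (nrow(src) == 0L) return(undefined_metric("no_source"))
  if (nrow(tgt) == 0L) return(undefined_metric("no_target"))
  mean(nearest_neighbor_distances(src, tgt, method = method))
}

#' Proximity count within a radius
#'
#' The number of source-phenotype cells whose nearest target-phenotype cell
#' lies within `radius` micrometres, boundary inclusive (a target at exactly
#' the radius counts). The 30 um default reflects the physiological range of
#' direct/indirect cell-cell interaction. Returns 0 when the core has no
#' target cells (no source cell can then have one nearby) and 0 when it has
#' no source cells.
#'
#' @inheritParams mean_nnd
#' @param radius Radius in micrometres (> 0).
#' @return Integer count in `[0, n_source]`.
#' @export
proximity_count <- function(table, source_phenotype = "CAF",
                            target_phenotype = "TAEC", radius = 30,
                            method = "grid") {
  stopifnot(is.numeric(radius), length(radius) == 1L, radius > 0)
  src <- xy_of(table, source_phenotype)
  if (nrow(src) == 0L) return(0L)
  tgt <- xy_of(table, target_phenotype)
  if (nrow(tgt) == 0L) return(0L)
  d <- nearest_neighbor_distances(src, tgt, method = method)
  sum(d <= radius)
}

#' Per-core spatial metrics
#'
#' Computes the full per-core metric row: total cells, density per 1000 for
#' CAF and TAEC phenotypes and PD-L1/PD-1 marker positivity, mean CAF->TAEC
#' nearest-neighbor distance, and the proximity count within `radius` (raw
#' and per 1000 cells). NND and proximity are reported as `NA` when the core
#' lacks either phenotype: an absent phenotype makes the spatial relationship
#' undefined, and reporting 0 would fake extreme proximity or distance.
#'
#' @param table A phenotyped [cell_table()] (phenotypes are assigned with the
#'   default rules if missing).
#' @param radius Proximity radius in micrometres.
#' @param source_phenotype,target_phenotype Phenotype pair for NND/proximity.
#' @return One-row tibble of core metrics.
#' @export
core_metrics <- function(table, radius = 30,
                         source_phenotype = "CAF", target_phenotype = "TAEC") {
  stopifnot(inherits(table, "cell_table"))
  if (!"phenotype" %in% names(table$cells)) {
    table <- assign_phenotypes(table)
  }
  n <- nrow(table$cells)
  nnd <- mean_nnd(table, source_phenotype, target_phenotype)
  n_src <- count_cells(table, phenotype = source_phenotype)
  n_tgt <- count_cells(table, phenotype = target_phenotype)
  prox <- if (n_src == 0L || n_tgt == 0L) NA_integer_ else {
    proximity_count(table, source_phenotype, target_phenotype, radius)
  }
  tibble::tibble(
    patient_id = table$patient_id,
    core_id = table$core_id,
    n_cells = n,
    n_source = n_src,
    n_target = n_tgt,
    density_CAF = as.numeric(density_per_1000(table, phenotype = source_phenotype)),
    density_TAEC = as.numeric(density_per_1000(table, phenotype = target_phenotype)),
    density_PDL1 = if ("PDL1" %in% table$markers)
      as.numeric(density_per_1000(table, marker = "PDL1")) else NA_real_,
    density_PD1 = if ("PD1" %in% table$markers)
      as.numeric(density_per_1000(table, marker = "PD1")) else NA_real_,
    mean_nnd_um = as.numeric(nnd),
    proximity_raw = as.numeric(prox),
    proximity_per1000 = if (is.na(prox) || n == 0L) NA_real_ else 1000 * prox / n,
    radius_um = radius
  )
}

#' Aggregate per-core metrics to one row per patient
#'
#' A patient contributes one value per metric, aggregated over that patient's
#' cores. Aggregation methods:
#' \describe{
#'   \item{`"mean"`}{(default) unweighted mean over cores where the metric is
#'     defined; the number of contributing cores is recorded.}
#'   \item{`"cell_weighted"`}{mean weighted by total cells per core for the
#'     densities and by source-cell count for NND/proximity.}
#'   \item{`"pooled"`}{all cells of all cores treated as one point set. Cores
#'     are laid side by side with a 10 mm gap before pooling so nearest
#'     neighbors never pair cells from different pieces of tissue.}
#' }
#'
#' @param cores List of phenotyped [cell_table()]s for one patient, or a
#'   precomputed per-core metrics tibble (for `"mean"`/`"cell_weighted"`).
#' @param radius Proximity radius in micrometres.
#' @param aggregation Aggregation method tag.
#' @param source_phenotype,target_phenotype Phenotype pair for NND/proximity.
#' @return One-row tibble of patient metrics, with `n_cores`, per-metric
#'   contributing core counts and the aggregation tag.
#' @export
patient_metrics <- function(cores, radius = 30,
                            aggregation = c("mean", "cell_weighted", "pooled"),
                            source_phenotype = "CAF", target_phenotype = "TAEC") {
  aggregation <- match.arg(aggregation)
  if (inherits(cores, "cell_table")) cores <- list(cores)
  if (is.data.frame(cores)) {
    per_core <- cores
    if (aggregation == "pooled") {
      stop("pooled aggregation needs the cell tables, not precomputed metrics",
           call. = FALSE)
    }
  } else {
    stopifnot(length(cores) >= 1L)
    pids <- unique(vapply(cores, function(tt) tt$patient_id, character(1)))
    if (length(pids) != 1L) {
      stop("patient_metrics() aggregates cores of a single patient; got: ",
           paste(pids, collapse = ", "), call. = FALSE)
    }
    if (aggregation == "pooled") {
      return(pooled_patient_metrics(cores, radius, source_phenotype,
                                    target_phenotype))
    }
    per_core <- dplyr::bind_rows(lapply(cores, core_metrics, radius = radius,
                                        source_phenotype = source_phenotype,
                                        target_phenotype = target_phenotype))
  }
  dens_cols <- c("density_CAF", "density_TAEC", "density_PDL1", "density_PD1")
  spat_cols <- c("mean_nnd_um", "proximity_raw", "proximity_per1000")
  wmean <- function(v, w) {
    ok <- !is.na(v) & !is.na(w) & w > 0
    if (!any(ok)) NA_real_ else sum(v[ok] * w[ok]) / sum(w[ok])
  }
  agg1 <- function(v, w) {
    if (aggregation == "mean") {
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    } else {
      wmean(v, w)
    }
  }
  out <- tibble::tibble(
    patient_id = per_core$patient_id[1],
    n_cores = nrow(per_core),
    n_cells = sum(per_core$n_cells)
  )
  for (cc in dens_cols) out[[cc]] <- agg1(per_core[[cc]], per_core$n_cells)
  for (cc in spat_cols) out[[cc]] <- agg1(per_core[[cc]], per_core$n_source)
  out$n_cores_nnd <- sum(!is.na(per_core$mean_nnd_um))
  out$radius_um <- per_core$radius_um[1]
  out$aggregation <- aggregation
  out
}

pooled_patient_metrics <- function(cores, radius, source_phenotype,
                                   target_phenotype) {
  gap <- 1e4  # 10 mm: wider than any plausible nearest-neighbor distance
  offset <- 0
  parts <- lapply(cores, function(tab) {
    d <- tab$cells
    d$x <- d$x + offset
    offset <<- offset + tab$width + gap
    d
  })
  all_cells <- dplyr::bind_rows(parts)
  all_cells$cell_id <- sprintf("pooled_%06d", seq_len(nrow(all_cells)))
  pooled <- cell_table(cores[[1]]$patient_id, "pooled", all_cells,
                       width = offset, height = max(vapply(cores, `[[`, 0, "height")),
                       markers = cores[[1]]$markers)
  out <- core_metrics(pooled, radius = radius,
                      source_phenotype = source_phenotype,
                      target_phenotype = target_phenotype)
  tibble::tibble(
    patient_id = out$patient_id,
    n_cores = length(cores),
    n_cells = out$n_cells,
    density_CAF = out$density_CAF, density_TAEC = out$density_TAEC,
    density_PDL1 = out$density_PDL1, density_PD1 = out$density_PD1,
    mean_nnd_um = out$mean_nnd_um,
    proximity_raw = out$proximity_raw,
    proximity_per1000 = out$proximity_per1000,
    n_cores_nnd = if (is.na(out$mean_nnd_um)) 0L else length(cores),
    radius_um = radius,
    aggregation = "pooled"
  )
}

#' Per-patient metrics for a whole cohort
#'
#' Convenience wrapper: groups a list of phenotyped cell tables by patient and
#' returns one [patient_metrics()] row per patient.
#'
#' @param tables Named or unnamed list of phenotyped [cell_table()]s.
#' @inheritParams patient_metrics
#' @return Tibble, one row per patient.
#' @export
cohort_metrics <- function(tables, radius = 30, aggregation = "mean",
                           source_phenotype = "CAF", target_phenotype = "TAEC") {
  pids <- vapply(tables, function(tt) tt$patient_id, character(1))
  rows <- lapply(split(tables, factor(pids, levels = unique(pids))),
                 patient_metrics, radius = radius, aggregation = aggregation,
                 source_phenotype = source_phenotype,
                 target_phenotype = target_phenotype)
  dplyr::bind_rows(rows)
}
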