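test_that("nearest-neighbor distances match hand geometry", {
  expect_equal(nearest_neighbor_distances(cbind(0, 0),
                                          rbind(c(3, 4), c(10, 0))), 5)
  expect_equal(nearest_neighbor_distances(rbind(c(0, 0), c(10, 0)),
                                          cbind(0, 0)), c(0, 10))
  expect_error(nearest_neighbor_distances(cbind(0, 0),
                                          matrix(numeric(0), ncol = 2)),
               "empty")
  expect_length(nearest_neighbor_distances(matrix(numeric(0), ncol = 2),
                                           cbind(0, 0)), 0L)
})

test_that("grid index agrees exactly with the all-pairs oracle", {
  set.seed(402)
  for (rep in 1:100) {
    ns <- sample(1:250, 1); nt <- sample(1:250, 1)
    w <- sample(c(10, 100, 1000), 1)
    src <- cbind(runif(ns, 0, w), runif(ns, 0, w))
    tgt <- cbind(runif(nt, 0, w), runif(nt, 0, w))
    # occasionally duplicate coordinates across the two sets
    if (rep %% 5 == 0 && nt > 1) tgt[1, ] <- src[1, ]
    g <- nearest_neighbor_distances(src, tgt, method = "grid")
    b <- nearest_neighbor_distances(src, tgt, method = "brute")
    expect_identical(g, b)
  }
  # degenerate geometries
  src <- cbind(rep(2, 4), rep(3, 4))
  tgt <- cbind(rep(2, 3), rep(3, 3))
  expect_identical(nearest_neighbor_distances(src, tgt, "grid"),
                   nearest_neighbor_distances(src, tgt, "brute"))
  src <- cbind(1:50, rep(0, 50))  # collinear
  tgt <- cbind(seq(0.5, 25, by = 0.5), rep(0, 50))
  expect_identical(nearest_neighbor_distances(src, tgt, "grid"),
                   nearest_neighbor_distances(src, tgt, "brute"))
})

test_that("density per 1000 follows its definition and scale invariance", {
  tab <- make_table(caf = matrix(runif(100, 0, 100), ncol = 2),
                    other = matrix(runif(1900, 0, 100), ncol = 2))
  expect_equal(density_per_1000(tab, "CAF"), 1000 * 50 / 1000)
  half <- make_table(caf = matrix(runif(50, 0, 100), ncol = 2),
                     other = matrix(runif(950, 0, 100), ncol = 2))
  expect_equal(density_per_1000(half, "CAF"), 50)
  expect_equal(density_per_1000(half, "TAEC"), 0)
  expect_equal(density_per_1000(half, marker = "PDL1"), 0)

  empty <- cell_table("P", "c",
                      tibble::tibble(cell_id = character(), x = numeric(),
                                     y = numeric(), CK = integer(),
                                     aSMA = integer(), CD31 = integer()),
                      width = 10, height = 10,
                      markers = c("CK", "aSMA", "CD31"))
  empty$cells$phenotype <- character()
  expect_true(is.na(density_per_1000(empty, "CAF")))
})

test_that("mean NND averages per-source minima and flags undefined sides", {
  tab <- make_table(caf = rbind(c(0, 0), c(0, 10)), taec = c(0, 4))
  expect_equal(mean_nnd(tab), 5)
  one <- make_table(caf = c(0, 0), taec = c(3, 4))
  expect_equal(mean_nnd(one), 5)

  no_src <- make_table(taec = c(1, 1), other = c(2, 2))
  expect_true(is.na(mean_nnd(no_src)))
  expect_equal(attr(mean_nnd(no_src), "reason"), "no_source")
  no_tgt <- make_table(caf = c(1, 1), other = c(2, 2))
  expect_equal(attr(mean_nnd(no_tgt), "reason"), "no_target")
})

test_that("proximity radius boundary is inclusive", {
  expect_equal(proximity_count(make_table(caf = c(0, 0), taec = c(0, 29.9))), 1L)
  expect_equal(proximity_count(make_table(caf = c(0, 0), taec = c(0, 30.0))), 1L)
  expect_equal(proximity_count(make_table(caf = c(0, 0), taec = c(0, 30.1))), 0L)
  expect_equal(proximity_count(make_table(taec = c(0, 1), other = c(5, 5))), 0L)
})

test_that("proximity count is monotone in the radius and saturates", {
  set.seed(403)
  tab <- make_table(caf = matrix(runif(80, 0, 200), ncol = 2),
                    taec = matrix(runif(40, 0, 200), ncol = 2))
  radii <- c(5, 10, 20, 30, 60, 120)
  counts <- vapply(radii, function(r) proximity_count(tab, radius = r),
                   integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(proximity_count(tab, radius = 1e6), 40L)  # all 40 CAFs
})

test_that("NND is rigid-motion invariant and scales linearly; densities do not", {
  set.seed(404)
  caf <- matrix(runif(60, 10, 90), ncol = 2)
  taec <- matrix(runif(30, 10, 90), ncol = 2)
  base <- make_table(caf = caf, taec = taec, width = 200, height = 200)
  v0 <- mean_nnd(base)

  shifted <- make_table(caf = caf + 40, taec = taec + 40,
                        width = 200, height = 200)
  expect_equal(mean_nnd(shifted), v0, tolerance = 1e-12)

  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- function(p) sweep(sweep(p, 2, c(50, 50)) %*% R, 2, c(-100, -100))
  rotated <- make_table(caf = rot(caf), taec = rot(taec),
                        width = 300, height = 300)
  expect_equal(mean_nnd(rotated), v0, tolerance = 1e-9)

  s <- 2.5
  scaled <- make_table(caf = caf * s, taec = taec * s,
                       width = 500, height = 500)
  expect_equal(mean_nnd(scaled), s * v0, tolerance = 1e-9)
  expect_equal(density_per_1000(scaled, "CAF"), density_per_1000(base, "CAF"))
})

test_that("adding a target cell never increases any nearest distance", {
  set.seed(405)
  for (rep in 1:10) {
    src <- matrix(runif(60, 0, 100), ncol = 2)
    tgt <- matrix(runif(20, 0, 100), ncol = 2)
    before <- nearest_neighbor_distances(src, tgt)
    after <- nearest_neighbor_distances(src, rbind(tgt, runif(2, 0, 100)))
    expect_true(all(after <= before + 1e-12))
  }
})

test_that("Poisson targets match the closed-form NND and proximity laws", {
  set.seed(406)
  lam <- 3e-4; W <- 1000; margin <- 60
  reps <- 16
  nnd_rep <- prox_rep <- numeric(reps)
  for (rep in seq_len(reps)) {
    nt <- rpois(1, lam * W * W)
    tgt <- cbind(runif(nt, 0, W), runif(nt, 0, W))
    src <- cbind(runif(300, margin, W - margin),
                 runif(300, margin, W - margin))
    d <- nearest_neighbor_distances(src, tgt)
    nnd_rep[rep] <- mean(d)
    prox_rep[rep] <- mean(d <= 30)
  }
  cf <- closed_form_checks(lam, r = 30)
  expect_within_3se(nnd_rep, cf$expected_nnd)
  expect_within_3se(prox_rep, cf$expected_proximity_prob)
})

test_that("patient aggregation follows the configured method", {
  set.seed(407)
  c1 <- make_table(caf = rbind(c(0, 0), c(0, 10)), taec = c(0, 4),
                   width = 100, height = 100, core = "c1")    # NND 5
  c2 <- make_table(caf = c(0, 0), taec = c(0, 15),
                   width = 100, height = 100, core = "c2")    # NND 15
  one <- patient_metrics(list(c1))
  expect_equal(one$mean_nnd_um, core_metrics(c1)$mean_nnd_um)
  expect_equal(one$n_cores, 1L)

  two <- patient_metrics(list(c1, c2))
  expect_equal(two$mean_nnd_um, (5 + 15) / 2)   # unweighted over cores
  cw <- patient_metrics(list(c1, c2), aggregation = "cell_weighted")
  expect_equal(cw$mean_nnd_um, (2 * 5 + 1 * 15) / 3)  # weighted by CAF count

  # a core without TAECs contributes to densities but not NND
  c3 <- make_table(caf = rbind(c(1, 1), c(2, 2)), other = c(3, 3),
                   width = 100, height = 100, core = "c3")
  mixed <- patient_metrics(list(c1, c3))
  expect_equal(mixed$mean_nnd_um, 5)
  expect_equal(mixed$n_cores_nnd, 1L)
  expect_equal(mixed$n_cores, 2L)
})

test_that("pooled aggregation keeps cores spatially disjoint", {
  c1 <- make_table(caf = c(0, 0), taec = c(0, 8),
                   width = 100, height = 100, core = "c1")
  c2 <- make_table(caf = c(50, 50), taec = c(50, 70),
                   width = 100, height = 100, core = "c2")
  pooled <- patient_metrics(list(c1, c2), aggregation = "pooled")
  # cross-core pairing would give distances < 8 or < 20; disjoint layout
  # must reproduce the per-core nearest neighbors exactly
  expect_equal(pooled$mean_nnd_um, (8 + 20) / 2)
  expect_equal(pooled$aggregation, "pooled")
})

test_that("cohort metrics return one row per patient", {
  set.seed(408)
  tabs <- list(
    make_table(caf = c(0, 0), taec = c(0, 3), patient = "A", core = "c1"),
    make_table(caf = c(0, 0), taec = c(0, 5), patient = "A", core = "c2"),
    make_table(caf = c(0, 0), taec = c(0, 7), patient = "B", core = "c1")
  )
  cm <- cohort_metrics(tabs)
  expect_equal(cm$patient_id, c("A", "B"))
  expect_equal(cm$mean_nnd_um, c(4, 7))
})
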