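# Field with two well-separated textures on a 12 x 12 grid: rows 1-6 hold
# texture A (thrombus-like), rows 7-12 texture B.
two_texture_field <- function(seed = 1) {
  a <- random_model(2, 9, seed = 600 + seed)
  b <- random_model(2, 9, seed = 700 + seed)
  jitter <- function(base, i) {
    set.seed(800 + i)
    toy_model(base$A, base$C + matrix(rnorm(18, sd = 0.03), 9, 2))
  }
  # models are stored column-major over the grid: texture A on the top
  # two grid rows (pixel rows 1-6), texture B below
  models <- lapply(1:16, function(m) {
    top <- ((m - 1) %% 4) < 2
    jitter(if (top) a else b, m)
  })
  f <- toy_field(models, grid_rows = seq(2, by = 3, length.out = 4),
                 grid_cols = seq(2, by = 3, length.out = 4), H = 12, W = 12)
  labels <- matrix(0L, 12, 12)
  labels[1:6, ] <- 2L   # thrombus-half
  list(field = f, labels = labels)
}

region_stats_for <- function(f, labels, event_map = NULL, seed = 1) {
  set.seed(seed)
  masks <- dyntexseg:::.region_masks(labels)
  out <- list()
  for (k in names(masks))
    if (any(masks[[k]]))
      out[[k]] <- region_statistics(f, masks[[k]], k, n_samples = 8,
                                    event_map = event_map)
  out
}

test_that("motion energy is lower at the true partition than under label swaps", {
  fx <- two_texture_field()
  stats <- region_stats_for(fx$field, fx$labels)
  e0 <- motion_segmentation_energy(fx$field, fx$labels, stats)
  set.seed(1)
  worse <- 0
  for (i in 1:10) {
    lab <- fx$labels
    px <- cbind(sample(12, 1), sample(12, 1))
    lab[px] <- if (lab[px] == 2L) 0L else 2L
    if (motion_segmentation_energy(fx$field, lab, stats) > e0) worse <- worse + 1
  }
  expect_gte(worse, 9)  # energy computed with fixed stats penalizes swaps
})

test_that("motion energy with one shared texture is relabel-invariant", {
  m <- random_model(2, 9, seed = 12)
  f <- toy_field(list(m, m, m, m), grid_rows = c(3, 9), grid_cols = c(3, 9),
                 H = 12, W = 12)
  labA <- matrix(0L, 12, 12); labA[1:6, ] <- 2L
  labB <- matrix(2L, 12, 12); labB[1:6, ] <- 0L
  st <- list(thrombus = region_statistics(f, labA == 2, "thrombus", 4),
             background = region_statistics(f, labA == 0, "background", 4))
  # swap the region statistics along with the labels
  stB <- list(thrombus = st$background, background = st$thrombus)
  stB$thrombus$region_id <- "thrombus"; stB$background$region_id <- "background"
  expect_equal(motion_segmentation_energy(f, labA, st),
               motion_segmentation_energy(f, labB, stB), tolerance = 1e-9)
})

test_that("empty regions contribute nothing and missing stats are an error", {
  fx <- two_texture_field()
  stats <- region_stats_for(fx$field, fx$labels)
  lab_all2 <- matrix(2L, 12, 12)
  e <- motion_segmentation_energy(fx$field, lab_all2, stats["thrombus"])
  expect_true(is.finite(e))  # vessel/background empty: empty sums
  expect_error(motion_segmentation_energy(fx$field, fx$labels, NULL),
               class = "dyntexseg_missing_stats")
  expect_error(motion_segmentation_energy(fx$field, fx$labels,
                                          list(thrombus = NULL)),
               class = "dyntexseg_missing_stats")
})

test_that("event map is zero between identical fields and flags swapped textures", {
  fx <- two_texture_field()
  em <- event_detection_map(fx$field, fx$field)
  expect_true(all(em$delta == 0))
  # swap: second window carries the textures exchanged between halves
  f2 <- fx$field
  perm <- vapply(1:16, function(m) {
    col <- (m - 1) %/% 4; row <- (m - 1) %% 4
    col * 4 + (row + 2) %% 4 + 1
  }, numeric(1))
  f2$models <- fx$field$models[perm]
  n <- 2
  f2$Q <- fx$field$Q[, as.vector(t(outer((perm - 1) * n, 1:n, `+`)))]
  em2 <- event_detection_map(fx$field, f2)
  expect_gt(mean(em2$delta), 1)
  # grid mismatch rejected
  f3 <- fx$field; f3$grid_rows <- f3$grid_rows + 1L
  expect_error(event_detection_map(fx$field, f3),
               class = "dyntexseg_grid_mismatch")
})

test_that("event energy matches its closed forms and a naive loop", {
  delta <- matrix(runif(64), 8, 8)
  labels <- matrix(0L, 8, 8); labels[1:4, ] <- 2L
  mkst <- function(mu, sd) list(region_id = "x", event_mean = mu, event_std = sd)
  # delta == mu everywhere, sigma = 1 -> zero
  stats0 <- list(thrombus = mkst(0.3, 1), background = mkst(0.3, 1))
  expect_equal(event_detection_energy(matrix(0.3, 8, 8), labels, stats0), 0)
  # doubling sigma with delta = mu adds |region| * log 2
  stats2 <- list(thrombus = mkst(0.3, 2), background = mkst(0.3, 1))
  expect_equal(event_detection_energy(matrix(0.3, 8, 8), labels, stats2),
               sum(labels == 2) * log(2), tolerance = 1e-12)
  # general case against an explicit loop
  stats <- list(thrombus = mkst(0.4, 0.2), background = mkst(0.1, 0.3))
  got <- event_detection_energy(delta, labels, stats)
  acc <- 0
  for (i in 1:8) for (j in 1:8) {
    st <- if (labels[i, j] == 2L) stats$thrombus else stats$background
    acc <- acc + (delta[i, j] - st$event_mean)^2 / (2 * st$event_std^2) +
      log(st$event_std)
  }
  expect_equal(got, acc, tolerance = 1e-12)
})

test_that("rectangle fit recovers an axis-aligned and a rotated band", {
  mask <- matrix(FALSE, 60, 80)
  mask[26:35, 21:60] <- TRUE  # 40 x 10 solid rectangle
  r <- fit_rectangle(mask)
  expect_lt(abs(r$slope), 1e-6)
  expect_equal(unname(r$center), c(40.5, 30.5), tolerance = 1e-9)
  expect_equal(r$radius, 5, tolerance = 0.5)
  # the same rectangle rotated 45 degrees
  mask45 <- matrix(FALSE, 80, 80)
  for (u in seq(-20, 20, by = 0.25)) for (v in seq(-4.5, 4.5, by = 0.25)) {
    x <- round(40 + (u - v) / sqrt(2)); y <- round(40 + (u + v) / sqrt(2))
    if (x >= 1 && x <= 80 && y >= 1 && y <= 80) mask45[y, x] <- TRUE
  }
  r45 <- fit_rectangle(mask45)
  expect_equal(abs(r45$slope), 1, tolerance = 0.05)
  expect_error(fit_rectangle(matrix(c(TRUE, rep(FALSE, 24)), 5, 5)),
               class = "dyntexseg_degenerate_mask")
})

test_that("rectangle fit is equivariant to a 90-degree rotation", {
  mask <- matrix(FALSE, 50, 70)
  mask[21:30, 11:60] <- TRUE
  r0 <- fit_rectangle(mask)
  r90 <- fit_rectangle(t(mask)[, rev(seq_len(50))])  # rotate 90 deg
  expect_equal(r90$radius, r0$radius, tolerance = 0.6)
  ang0 <- r0$angle %% pi
  ang90 <- r90$angle %% pi
  expect_equal(abs(ang90 - ang0) %% pi, pi / 2, tolerance = 0.05)
})

test_that("shape prior energy follows the exponential distance penalty", {
  rect <- structure(list(slope = 0, center = c(16, 10), radius = 4,
                         angle = 0), class = "dts_rectangle")
  labels <- matrix(0L, 20, 32)
  labels[7:13, ] <- 1L  # vessel entirely inside the band
  expect_equal(shape_prior_energy(labels, rect, sigma_sp = 5), 0)
  expect_equal(shape_prior_energy(matrix(0L, 20, 32), rect, 5), 0)
  # one pixel at distance d with d^2 = 2 sigma^2 ln 2 contributes exactly 1
  sigma <- 3
  d <- sqrt(2 * sigma^2 * log(2))
  labels2 <- labels
  px_row <- 10 + 4 + round(d)  # approximately at distance d below the band
  labels2[px_row, 16] <- 1L
  dmap <- dyntexseg:::rectangle_distance(rect, 20, 32)
  expected <- expm1(dmap[px_row, 16]^2 / (2 * sigma^2))
  expect_equal(shape_prior_energy(labels2, rect, sigma), expected,
               tolerance = 1e-9)
  expect_gt(expected, 0.5)  # near the unit contribution by construction
})

test_that("topological energy counts the forbidden overlap", {
  phi1 <- matrix(5, 10, 10)
  phi2 <- matrix(-5, 10, 10)
  expect_lt(topological_energy(phi1, phi2), 1e-9)  # phi1 > 0 everywhere
  # sharp limit: k pixels with phi1 < 0 and phi2 > 0
  phi1s <- matrix(100, 10, 10); phi2s <- matrix(-100, 10, 10)
  phi1s[1:3, 1:4] <- -100; phi2s[1:3, 1:4] <- 100
  expect_equal(topological_energy(phi1s, phi2s), 12, tolerance = 1e-9)
  # monotone under growing the forbidden set
  phi1b <- phi1s; phi2b <- phi2s
  phi1b[4, 1:4] <- -100; phi2b[4, 1:4] <- 100
  expect_gte(topological_energy(phi1b, phi2b),
             topological_energy(phi1s, phi2s))
})

test_that("total energy combines the printed weighted sum and is linear", {
  expect_equal(total_energy(3, 2, 7, 1, alpha = 0, beta = 0, gamma = 0,
                            zeta = 0), 0)
  expect_equal(total_energy(3, 2, 7, 1), 1 * 3 + 0.5 * 2 - 0.1 * 7 + 1.25 * 1)
  # linearity in each weight
  base <- total_energy(3, 2, 7, 1, alpha = 1)
  up <- total_energy(3, 2, 7, 1, alpha = 1.5)
  expect_equal(up - base, 0.5 * 3, tolerance = 1e-12)
  expect_equal(total_energy(5, NULL, NA, 2, zeta = 2), 5 + 4)
})
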