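# A 4 x 4 grid of random models on a 12 x 12 image, used throughout.
stats_fixture <- function(seed = 1, nm = 16) {
  side <- sqrt(nm)
  models <- lapply(seq_len(nm), function(i) random_model(2, 9, seed * 1000 + i))
  toy_field(models, grid_rows = seq(2, by = 3, length.out = side),
            grid_cols = seq(2, by = 3, length.out = side), H = 12, W = 12)
}

test_that("confidence weights follow the capped squared boundary distance", {
  mask <- matrix(FALSE, 30, 30)
  mask[3:28, 3:28] <- TRUE
  # boundary pixel, depth 2, and deep interior (distance 10 >= cap)
  pos <- rbind(c(3, 15), c(5, 15), c(15, 15))
  raw <- confidence_weights(mask, pos, patch_side = 5, normalize = FALSE)
  expect_equal(raw, c(0, 4, 25))
  w <- confidence_weights(mask, pos, patch_side = 5)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_error(confidence_weights(matrix(FALSE, 4, 4), rbind(c(1, 1))),
               class = "dyntexseg_empty_region")
})

test_that("sampled Frechet mean equals exhaustive brute force", {
  for (seed in 1:6) {
    f <- stats_fixture(seed)
    set.seed(seed)
    spos <- dyntexseg:::field_model_pixels(f)[sample(16, 8), , drop = FALSE]
    w <- runif(8); w <- w / sum(w)
    fm <- frechet_mean(f, spos, w)
    # brute force over every candidate with plain martin_distance calls
    si <- dyntexseg:::field_index_at(f, spos)
    obj <- vapply(seq_along(f$models), function(ci) {
      sum(w * vapply(si, function(yi)
        min(martin_distance(f$models[[ci]], f$models[[yi]]), 1e6),
        numeric(1)))
    }, numeric(1))
    expect_equal(attr(fm, "index"), which.min(obj))
    expect_equal(attr(fm, "objective"), min(obj), tolerance = 1e-12)
  }
})

test_that("Frechet mean returns the sample model itself when all samples agree", {
  f <- stats_fixture(2)
  pos <- dyntexseg:::field_model_pixels(f)[5, , drop = FALSE]
  fm <- frechet_mean(f, pos, 1)
  expect_equal(attr(fm, "index"), 5L)
  expect_equal(attr(fm, "objective"), 0)
})

test_that("ties break to the lowest linear pixel index", {
  m <- random_model(2, 9, seed = 9)
  models <- list(m, m, m, m)   # all candidates equidistant from any sample
  f <- toy_field(models, grid_rows = c(2, 8), grid_cols = c(2, 8),
                 H = 10, W = 10)
  fm <- frechet_mean(f, rbind(c(8, 8)), 1)
  expect_equal(attr(fm, "index"), 1L)  # grid (2,2): lowest column-major index
})

test_that("Doss squared distance matches an independent accumulation", {
  f <- stats_fixture(3)
  x <- random_model(2, 9, seed = 77)
  set.seed(3)
  spos <- dyntexseg:::field_model_pixels(f)[sample(16, 10), , drop = FALSE]
  w <- runif(10); w <- w / sum(w)
  got <- doss_sq_distance(x, f, spos, w)
  si <- dyntexseg:::field_index_at(f, spos)
  acc <- 0
  for (i in seq_along(si))
    acc <- acc + w[i] * min(martin_distance(x, f$models[[si[i]]]), 1e6)
  expect_equal(got, acc, tolerance = 1e-12)
  # single sample with weight one is the plain squared distance
  one <- dyntexseg:::field_model_pixels(f)[4, , drop = FALSE]
  expect_equal(doss_sq_distance(x, f, one, 1),
               martin_distance(x, f$models[[4]]), tolerance = 1e-12)
  # a model measured against itself alone is at distance zero
  self <- doss_sq_distance(f$models[[4]], f, one, 1)
  expect_lt(self, 1e-9)
  expect_error(doss_sq_distance(x, f, matrix(0L, 0, 2)),
               class = "dyntexseg_empty_samples")
})

test_that("region variance: identical models give the floor, two models expand", {
  m <- random_model(2, 9, seed = 5)
  f1 <- toy_field(list(m, m, m, m), grid_rows = c(2, 8), grid_cols = c(2, 8),
                  H = 10, W = 10)
  mask <- matrix(TRUE, 10, 10)
  v <- region_variance(f1, mask, mean = structure(m, index = 1L))
  expect_equal(v, 1e-6)  # all distances vanish -> floored
  # two distinct models at squared distance c, equal confidence weights,
  # Doss mode with both as samples: every pixel's surrogate distance is
  # c/2, so the variance is c/2
  m2 <- random_model(2, 9, seed = 6)
  cc <- martin_distance(m, m2)
  f2 <- toy_field(list(m, m2), grid_rows = c(3, 9), grid_cols = 6,
                  H = 12, W = 12)
  mask2 <- matrix(TRUE, 12, 12)
  spos <- rbind(c(3, 6), c(9, 6))
  v2 <- region_variance(f2, mask2, samples = spos,
                        sample_weights = c(0.5, 0.5))
  expect_equal(v2, cc / 2, tolerance = 1e-10)
})

test_that("region log-likelihood matches d^2/(2 sigma^2) + log sigma", {
  f <- stats_fixture(4)
  set.seed(4)
  st <- region_statistics(f, matrix(TRUE, 12, 12), "vessel",
                          n_samples = 8, mean_mode = "frechet")
  x <- st$frechet_mean
  expect_equal(region_log_likelihood(x, st, f), 0.5 * log(st$variance),
               tolerance = 1e-9)
  y <- random_model(2, 9, seed = 55)
  d2 <- min(martin_distance(y, st$frechet_mean), 1e6)
  expect_equal(region_log_likelihood(y, st, f),
               d2 / (2 * st$variance) + 0.5 * log(st$variance),
               tolerance = 1e-9)
})

test_that("region statistics are normalized, reproducible, and Doss-consistent", {
  f <- stats_fixture(5)
  mask <- matrix(TRUE, 12, 12)
  set.seed(99)
  st1 <- region_statistics(f, mask, "thrombus", n_samples = 6)
  set.seed(99)
  st2 <- region_statistics(f, mask, "thrombus", n_samples = 6)
  expect_identical(st1$sample_positions, st2$sample_positions)
  expect_identical(st1$d2_grid, st2$d2_grid)
  expect_equal(sum(st1$sample_weights), 1, tolerance = 1e-12)
  expect_gte(st1$variance, 0)
})

test_that("Doss surrogate dominates the Frechet distance on tight clusters", {
  # Soft property. Euclidean analogy: doss(x) = d(x, mu)^2 + V while the
  # sampled mean sits at offset delta <= sqrt(V) from mu, so
  # frechet(x) - doss(x) <= 2 d delta + delta^2 - V <= 2 V for probes
  # inside the cluster (d <= sqrt(V)); checked with that slack on >= 90%
  # of probes.
  hits <- 0; total <- 0
  for (seed in 1:4) {
    base <- random_model(2, 9, seed = 300 + seed)
    models <- lapply(1:9, function(i) {
      set.seed(400 + seed * 10 + i)
      P <- base$C + matrix(rnorm(18, sd = 0.05), 9, 2)
      toy_model(base$A, P)
    })
    f <- toy_field(models, grid_rows = seq(2, by = 3, length.out = 3),
                   grid_cols = seq(2, by = 3, length.out = 3), H = 9, W = 9)
    mp <- dyntexseg:::field_model_pixels(f)
    D <- dyntexseg:::field_martin_cross(f, 1:9, 1:9)
    v_hat <- mean(D[upper.tri(D)]) / 2   # cluster variance estimate
    set.seed(seed)
    fm <- frechet_mean(f, mp, rep(1 / 9, 9))
    for (i in 1:9) {
      total <- total + 1
      doss <- doss_sq_distance(f$models[[i]], f, mp, rep(1 / 9, 9))
      frch <- min(martin_distance(f$models[[i]], fm), 1e6)
      if (doss >= frch - 2 * v_hat) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.9)
})
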