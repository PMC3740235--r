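test_that("smooth Heaviside/Dirac satisfy the regularization contract", {
  phi <- seq(-6, 6, by = 0.25)
  H <- smooth_heaviside(phi, 1.5)
  expect_equal(smooth_heaviside(0, 1.5), 0.5)
  expect_true(all(diff(H) >= -1e-12))
  expect_equal(smooth_heaviside(phi, 1.5) + smooth_heaviside(-phi, 1.5),
               rep(1, length(phi)), tolerance = 1e-12)
  expect_equal(range(H), c(0, 1))
  d <- smooth_dirac(phi, 1.5)
  expect_true(all(d >= 0))
  expect_equal(d, rev(d), tolerance = 1e-12)
  # integral of delta along a line crossing the zero set is ~1
  x <- seq(-10, 10, by = 0.01)
  expect_equal(sum(smooth_dirac(x, 1.5)) * 0.01, 1, tolerance = 1e-3)
})

test_that("the four sign classes tile the image", {
  set.seed(1)
  phi1 <- matrix(rnorm(400), 20, 20)
  phi2 <- matrix(rnorm(400), 20, 20)
  lab <- levelset_labels(phi1, phi2)
  expect_true(all(lab %in% 0:3))
  expect_equal(sum(lab == 2), sum(phi1 < 0 & phi2 < 0))
  expect_equal(sum(lab == 1), sum(phi1 >= 0 & phi2 < 0))
  expect_equal(sum(lab == 3), sum(phi1 < 0 & phi2 >= 0))
  lab2 <- levelset_labels(NULL, phi2, inside_label = 2L)
  expect_setequal(unique(as.vector(lab2)), c(0L, 2L))
})

test_that("signed distance matches a brute-force nearest-opposite scan", {
  mask <- matrix(FALSE, 15, 15)
  mask[4:9, 5:12] <- TRUE
  mask[8:11, 3:6] <- TRUE
  phi <- signed_distance(mask)
  inpos <- which(mask, arr.ind = TRUE)
  outpos <- which(!mask, arr.ind = TRUE)
  brute <- function(p, ref) sqrt(min((ref[, 1] - p[1])^2 + (ref[, 2] - p[2])^2))
  set.seed(2)
  for (i in sample(nrow(inpos), 10)) {
    p <- inpos[i, ]
    expect_equal(phi[p[1], p[2]], -brute(p, outpos), tolerance = 1e-9)
  }
  for (i in sample(nrow(outpos), 10)) {
    p <- outpos[i, ]
    expect_equal(phi[p[1], p[2]], brute(p, inpos), tolerance = 1e-9)
  }
  expect_true(all(signed_distance(matrix(FALSE, 5, 5)) > 0))
})

test_that("polygon initialization rasterizes, clips, and validates", {
  sq <- rbind(c(3, 3), c(3, 10), c(10, 10), c(10, 3))
  ip <- init_from_polygons(sq, NULL, c(14, 14))
  inside <- ip$phi2 < 0
  expect_true(all(inside[4:9, 4:9]))
  expect_false(any(inside[12:14, ]))
  # thrombus clipped to the vessel polygon
  tp <- rbind(c(6, 6), c(6, 20), c(20, 20), c(20, 6))
  ip2 <- init_from_polygons(sq, tp, c(22, 22))
  expect_true(all(which(ip2$phi1 < 0, arr.ind = TRUE)[, 1] <= 10))
  expect_error(rasterize_polygon(rbind(c(1, 1), c(2, 2)), 10, 10),
               class = "dyntexseg_degenerate_polygon")
  far <- rbind(c(30, 30), c(30, 35), c(35, 35))
  expect_error(init_from_polygons(sq, far, c(22, 22)),
               class = "dyntexseg_degenerate_polygon")
})

test_that("diffusion coefficient follows the image gradient", {
  flat <- matrix(0.5, 10, 10)
  g <- diffusion_coefficient(flat, matrix(TRUE, 10, 10))
  expect_true(all(g == 1))  # eta = 0 convention
  ramp <- matrix(rep(seq(0, 1, length.out = 20), each = 10), 10, 20)
  g2 <- diffusion_coefficient(ramp, NULL, eta = NULL)
  expect_true(all(g2 == 1))  # no band -> g = 1
  gm <- dyntexseg:::.gradient_magnitude(ramp)
  g3 <- diffusion_coefficient(ramp, eta = gm[5, 10]^2)
  expect_equal(g3[5, 10], 0.5, tolerance = 1e-9)
  # strictly decreasing in |grad I|
  expect_true(all(diff(1 / (1 + (0:10)^2 / 2)) < 0))
})

test_that("gradient flow: zero weights leave the state unchanged", {
  set.seed(3)
  phi2 <- signed_distance(matrix(c(rep(TRUE, 50), rep(FALSE, 50)), 10, 10))
  cfg <- solver_config(alpha = 0, beta = 0, gamma = 0, zeta = 0,
                       lambda_d = 0, tau = 20, n = 2)
  out <- gradient_flow_step(list(phi1 = NULL, phi2 = phi2), NULL, NULL,
                            list(), NULL, cfg)
  expect_equal(out$phi2, phi2)
})

test_that("pure diffusion decreases total variation", {
  set.seed(4)
  phi <- matrix(rnorm(400), 20, 20)
  cfg <- solver_config(alpha = 0, beta = 0, gamma = 0, zeta = 0,
                       kappa = 0, lambda_d = 0.2, tau = 20, n = 2)
  tv <- function(f) sum(abs(diff(f))) + sum(abs(t(diff(t(f)))))
  out <- gradient_flow_step(list(phi1 = NULL, phi2 = phi), NULL, NULL,
                            list(), NULL, cfg)
  expect_lt(tv(out$phi2), tv(phi))
})

test_that("a flow step from near-truth does not worsen the label map", {
  sc <- make_scene(disk_square_scene(T = 40, seed = 8))
  cfg <- scene_config(8, tau = 39, max_outer = 1, max_inner = 1)
  phi1 <- signed_distance(sc$labels == 2)
  phi2 <- signed_distance(sc$labels >= 1)
  h0 <- 0  # truth init: Hamming distance starts at zero
  res <- segment(sc$sequence, c(1, 40), init = list(phi1 = phi1, phi2 = phi2),
                 config = cfg)
  h1 <- mean(res$labels != sc$labels)
  expect_lte(h1, 0.03)  # a single step stays in the truth basin
})

test_that("max_outer = 0 returns the initial partition unchanged", {
  sc <- make_scene(disk_square_scene(T = 40, seed = 2))
  phi1 <- signed_distance(sc$labels == 2)
  phi2 <- signed_distance(sc$labels >= 1)
  cfg <- scene_config(1, tau = 39, max_outer = 0)
  res <- segment(sc$sequence, c(1, 40), init = list(phi1 = phi1, phi2 = phi2),
                 config = cfg)
  expect_identical(res$labels, sc$labels)
})

test_that("segmentation is bit-identical for a fixed seed", {
  sc <- make_scene(disk_square_scene(T = 50, seed = 5))
  polys <- scene_polys()
  cfg <- scene_config(5, tau = 49, max_outer = 6)
  r1 <- segment(sc$sequence, c(1, 50), init = polys, config = cfg)
  r2 <- segment(sc$sequence, c(1, 50), init = polys, config = cfg)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$phi2, r2$phi2)
})

test_that("the flow decreases the smooth energy on most steps (fixed stats)", {
  sc <- make_scene(disk_square_scene(T = 50, seed = 6))
  cfg <- scene_config(6, tau = 49, max_outer = 2)
  res <- segment(sc$sequence, c(1, 50), init = scene_polys(), config = cfg)
  f <- res$field; stats <- res$stats
  emap <- function(st) matrix(pmin(st$d2_grid[f$index_map] /
                                     (2 * st$variance) +
                                     0.5 * log(st$variance), cfg$nll_cap),
                              f$H, f$W)
  e1 <- emap(stats$thrombus); e2 <- emap(stats$vessel)
  e3 <- emap(stats$background)
  smooth_E <- function(p1, p2) {
    H1 <- smooth_heaviside(p1, cfg$eps_h); H2 <- smooth_heaviside(p2, cfg$eps_h)
    sum(e1 * (1 - H1) * (1 - H2) + e2 * H1 * (1 - H2) + e3 * H1 * H2) +
      cfg$zeta * sum((1 - H1) * H2)
  }
  st <- list(phi1 = res$phi1, phi2 = res$phi2)
  es <- smooth_E(st$phi1, st$phi2)
  for (i in 1:10) {
    st <- gradient_flow_step(st, f, NULL, stats, NULL, cfg)
    es <- c(es, smooth_E(st$phi1, st$phi2))
  }
  expect_gte(mean(diff(es) <= 1e-9), 0.9)
})

test_that("solver configuration round-trips through YAML", {
  cfg <- solver_config(alpha = 2, beta = 0.25, n = 3, tau = 30,
                       mean_mode = "frechet", seed = 9)
  path <- tempfile(fileext = ".yaml")
  write_config(path, cfg)
  cfg2 <- read_config(path)
  expect_equal(cfg2[names(cfg2) != "nll_cap"], cfg[names(cfg) != "nll_cap"])
  writeLines("bogus_key: 1", path)
  expect_error(read_config(path), class = "dyntexseg_degenerate_input")
  unlink(path)
})
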