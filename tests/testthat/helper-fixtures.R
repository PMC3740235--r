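# Shared fixtures built in code.

# A dt_model with given (A, C); C columns are orthonormalized.
toy_model <- function(A, C, ybar = NULL) {
  C <- qr.Q(qr(as.matrix(C)))[, seq_len(ncol(as.matrix(C))), drop = FALSE]
  A <- as.matrix(A)
  # canonical sign (largest-magnitude entry of each column positive),
  # applied as a similarity transform so the model is unchanged
  sg <- vapply(seq_len(ncol(C)),
               function(j) sign(C[which.max(abs(C[, j])), j]), numeric(1))
  C <- sweep(C, 2, sg, `*`)
  A <- diag(sg, ncol(C)) %*% A %*% diag(sg, ncol(C))
  structure(list(A = A, C = C, ybar = ybar %||% rep(0.5, nrow(C)),
                 n = ncol(C), p = nrow(C), degenerate = FALSE),
            class = "dt_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random stable dt_model (order n, patch pixels p).
random_model <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n, n)
  A <- A * (0.9 / max(abs(eigen(A, only.values = TRUE)$values)))
  toy_model(A, matrix(rnorm(p * n), p, n))
}

# Hand-built dt_field holding `models` on an H x W pixel grid with one
# model per listed grid position (stride 1 over those rows/cols).
toy_field <- function(models, grid_rows, grid_cols, H, W,
                      patch_side = 3L, window = c(1L, 31L)) {
  n <- models[[1]]$n; p <- models[[1]]$p
  Q <- matrix(0, p * n, n * length(models))
  for (m in seq_along(models))
    Q[, ((m - 1) * n + 1):(m * n)] <- dyntexseg:::.obs_basis(models[[m]])
  nearest <- function(i, g) which.min(abs(g - i))
  row_idx <- vapply(seq_len(H), nearest, integer(1), g = grid_rows)
  col_idx <- vapply(seq_len(W), nearest, integer(1), g = grid_cols)
  index_map <- outer(row_idx, (col_idx - 1L) * length(grid_rows), `+`)
  structure(list(models = models, Q = Q,
                 degenerate = vapply(models, `[[`, logical(1), "degenerate"),
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 H = as.integer(H), W = as.integer(W),
                 patch_side = as.integer(patch_side), stride = 1L,
                 n = as.integer(n), window = as.integer(window),
                 index_map = index_map),
            class = "dt_field")
}

# Noise-free sustained-oscillation LDS patch stack: rotation with spectral
# radius just below 1 over whole periods, so the temporal mean of the
# state is negligible and the closed-form estimate recovers the subspace.
oscillating_stack <- function(n = 2, p = 25, T = 60, periods = 6, seed = 1,
                              rho = 0.999) {
  set.seed(seed)
  th <- 2 * pi * periods / T
  A <- rho * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  if (n > 2) {
    A2 <- matrix(0, n, n)
    A2[1:2, 1:2] <- A
    diag(A2)[seq(3, n)] <- rho * 0.5
    A <- A2
  }
  C <- qr.Q(qr(matrix(rnorm(p * n), p, n)))[, 1:n, drop = FALSE]
  z <- c(1, rep(0.5, n - 1))
  Y <- matrix(0, p, T)
  for (t in seq_len(T)) {
    Y[, t] <- 0.5 + C %*% z
    z <- A %*% z
  }
  list(Y = Y, truth = toy_model(A, C))
}

# Polygon fixtures for the 64 x 64 disk-in-square scene.
scene_polys <- function() {
  list(vessel = rbind(c(8, 14), c(10, 56), c(52, 58), c(56, 10)),
       thrombus = rbind(c(22, 20), c(24, 42), c(44, 40), c(40, 18)))
}

# Solver configuration matched to the wave-texture generators.
scene_config <- function(seed, mean_mode = "doss", zeta = 1.25, tau = 74,
                         max_outer = 40, max_inner = 4, ...) {
  solver_config(alpha = 1, beta = 0, gamma = 0, zeta = zeta,
                n = 2, tau = tau, patch_side = 3, stride = 1,
                n_samples = 40, mean_mode = mean_mode,
                max_outer = max_outer, max_inner = max_inner,
                kappa = 0.4, seed = seed, ...)
}
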