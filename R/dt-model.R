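#' Estimate a dynamic-texture model from a spatio-temporal patch
#'
#' Fits an order-`n` linear dynamical system to the intensities of one
#' spatial patch observed over a temporal window:
#' \deqn{z(t+1) = A z(t) + v(t), \qquad y(t) - \bar y = C z(t) + w(t)}
#' with `C` orthonormal.  The closed-form subspace estimate is used: with
#' the temporal mean removed, the SVD \eqn{Y = U \Sigma V^\top} gives
#' \eqn{\hat C = U_{1:n}}, state trajectory \eqn{\hat Z = \Sigma V^\top},
#' and \eqn{\hat A = \hat Z_{2:T} \hat Z_{1:T-1}^\dagger} (Moore–Penrose
#' pseudo-inverse).
#'
#' @param patch_stack numeric matrix, `p x (tau+1)`: one column per frame,
#'   one row per patch pixel.
#' @param n model order (positive integer, `n <= p` and `n <= tau`).
#' @param rank_tol singular values below `rank_tol * s1` count as zero;
#'   if fewer than `n` directions survive, the missing columns of `C` are
#'   padded with an orthonormal completion, the corresponding rows/columns
#'   of `A` are zeroed, and the model is flagged `degenerate` (legitimate
#'   for near-constant background patches).
#' @return object of class `dt_model`: list with `A` (n x n), `C` (p x n,
#'   orthonormal columns), `ybar` (length p), `n`, `p`, `degenerate`.
#' @seealso [martin_distance()], [compute_dt_field()]
#' @export
estimate_dt <- function(patch_stack, n, rank_tol = 1e-10) {
  patch_stack <- as.matrix(patch_stack)
  if (!all(is.finite(patch_stack)))
    stop_dts("degenerate_input", "patch_stack contains non-finite values")
  p <- nrow(patch_stack)
  tau <- ncol(patch_stack) - 1L          # number of state transitions
  if (n < 1L || n > p)
    stop_dts("degenerate_input", "order n=%d outside 1..p=%d", n, p)
  if (tau < n)
    stop_dts("insufficient_frames",
             "window has tau=%d transitions, need at least n=%d", tau, n)
  ybar <- rowMeans(patch_stack)
  Yc <- patch_stack - ybar
  sv <- svd(Yc)
  r <- sum(sv$d > rank_tol * max(sv$d[1], .Machine$double.eps))
  r <- min(r, n)
  degenerate <- r < n
  C <- matrix(0, p, n)
  if (r > 0) C[, seq_len(r)] <- sv$u[, seq_len(r), drop = FALSE]
  if (degenerate) C <- .complete_orthonormal(C, r)
  A <- matrix(0, n, n)
  if (r > 0) {
    Z <- diag(sv$d[seq_len(r)], r, r) %*% t(sv$v[, seq_len(r), drop = FALSE])
    A[seq_len(r), seq_len(r)] <-
      Z[, 2:(tau + 1), drop = FALSE] %*%
      MASS::ginv(Z[, 1:tau, drop = FALSE])
  }
  structure(list(A = A, C = C, ybar = ybar, n = as.integer(n),
                 p = as.integer(p), degenerate = degenerate),
            class = "dt_model")
}

# Pad columns (r+1)..n of C with canonical basis vectors orthogonalized
# against the existing columns (Gram-Schmidt over e_1, e_2, ...).
.complete_orthonormal <- function(C, r) {
  p <- nrow(C); n <- ncol(C)
  k <- r
  for (j in seq_len(p)) {
    if (k >= n) break
    v <- numeric(p); v[j] <- 1
    if (k > 0) {
      B <- C[, seq_len(k), drop = FALSE]
      v <- v - B %*% crossprod(B, v)
    }
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) {
      k <- k + 1L
      C[, k] <- v / nv
    }
  }
  C
}

#' Observability matrix of a dynamic-texture model
#'
#' Stacks the blocks \eqn{C, CA, \dots, CA^{n-1}} into a `(p*n) x n`
#' matrix.  Its column space characterizes the model up to a change of
#' state basis, and is what the Martin distance compares.
#'
#' @param model a `dt_model`.
#' @return numeric matrix `(p*n) x n`.
#' @export
observability_matrix <- function(model) {
  stopifnot(inherits(model, "dt_model"))
  n <- model$n; p <- model$p
  O <- matrix(0, p * n, n)
  blk <- model$C
  for (k in seq_len(n)) {
    O[((k - 1) * p + 1):(k * p), ] <- blk
    if (k < n) blk <- blk %*% model$A
  }
  O
}

# Orthonormal basis of the observability subspace (pn x n).
.obs_basis <- function(model) {
  O <- observability_matrix(model)
  qr.Q(qr(O))[, seq_len(model$n), drop = FALSE]
}

#' Squared Martin distance between two dynamic-texture models
#'
#' \deqn{d_M^2(D_1, D_2) = -\log \prod_i \cos^2\theta_i}
#' where \eqn{\theta_i} are the principal angles between the observability
#' subspaces of the two models.  Computed by orthonormalizing each
#' observability matrix and taking the singular values of the crossproduct
#' (clamped to `[0, 1]`); the determinant form of the same quantity is
#' numerically unstable when `p*n >> n`.  Returns `Inf` when any principal
#' angle is a right angle (`cos^2` below 1e-300); callers that feed
#' distances into statistics clamp at a finite cap.
#'
#' @param d1,d2 `dt_model` objects of equal order and patch size.
#' @return nonnegative scalar (possibly `Inf`); symmetric in its
#'   arguments; zero for identical models.
#' @export
martin_distance <- function(d1, d2) {
  stopifnot(inherits(d1, "dt_model"), inherits(d2, "dt_model"))
  if (d1$n != d2$n || d1$p != d2$p)
    stop_dts("order_mismatch",
             "models differ in order (%d vs %d) or patch size (%d vs %d)",
             d1$n, d2$n, d1$p, d2$p)
  Q1 <- .obs_basis(d1); Q2 <- .obs_basis(d2)
  s <- svd(crossprod(Q1, Q2))$d
  s <- pmin(pmax(s, 0), 1)
  c2 <- s^2
  if (any(c2 < 1e-300)) return(Inf)
  max(0, -sum(log(c2)))
}

#' Grid of dynamic-texture models over one temporal window
#'
#' Estimates a `dt_model` at every grid position (optionally strided)
#' whose full `patch_side x patch_side` patch fits in the image, over the
#' frames `window[1]..window[2]` (inclusive, 1-based).  Pixels nearer than
#' `patch_side/2` to the border carry no model; for energy evaluation
#' every pixel is mapped to the nearest modelled grid position
#' (`index_map`).
#'
#' @param sequence numeric array `H x W x T` of intensities.
#' @param window integer pair `c(first, last)` frame indices; the window
#'   spans `tau + 1 = last - first + 1` frames.
#' @param patch_side odd integer, spatial patch side in pixels.
#' @param n model order.
#' @param stride grid stride in pixels (default 1 = per-pixel models).
#' @return object of class `dt_field`: the model list, an orthonormal
#'   observability-basis bank used by the distance kernel, the grid
#'   geometry, and `index_map` (`H x W`, nearest model index, `NA` outside
#'   any model's reach never occurs since lookup is clamped).
#' @export
compute_dt_field <- function(sequence, window, patch_side = 5L, n = 3L,
                             stride = 1L) {
  dm <- dim(sequence)
  stopifnot(length(dm) == 3L)
  H <- dm[1]; W <- dm[2]; T <- dm[3]
  if (patch_side %% 2L != 1L)
    stop_dts("degenerate_input", "patch_side must be odd")
  if (window[1] < 1L || window[2] > T || window[2] <= window[1])
    stop_dts("window_out_of_range",
             "window [%d, %d] outside sequence of %d frames",
             window[1], window[2], T)
  r <- (patch_side - 1L) %/% 2L
  grid_rows <- seq.int(r + 1L, H - r, by = stride)
  grid_cols <- seq.int(r + 1L, W - r, by = stride)
  frames <- window[1]:window[2]
  p <- patch_side^2
  nmod <- length(grid_rows) * length(grid_cols)
  models <- vector("list", nmod)
  Q <- matrix(0, p * n, n * nmod)
  degenerate <- logical(nmod)
  m <- 0L
  for (gc in grid_cols) {
    for (gr in grid_rows) {
      m <- m + 1L
      patch <- sequence[(gr - r):(gr + r), (gc - r):(gc + r), frames]
      dim(patch) <- c(p, length(frames))
      mod <- estimate_dt(patch, n)
      models[[m]] <- mod
      degenerate[m] <- mod$degenerate
      Q[, ((m - 1L) * n + 1L):(m * n)] <- .obs_basis(mod)
    }
  }
  # nearest modelled grid position for every pixel
  row_idx <- pmin(pmax(round((seq_len(H) - grid_rows[1]) / stride) + 1L, 1L),
                  length(grid_rows))
  col_idx <- pmin(pmax(round((seq_len(W) - grid_cols[1]) / stride) + 1L, 1L),
                  length(grid_cols))
  index_map <- outer(row_idx, (col_idx - 1L) * length(grid_rows), `+`)
  structure(list(models = models, Q = Q, degenerate = degenerate,
                 grid_rows = grid_rows, grid_cols = grid_cols,
                 H = H, W = W, patch_side = as.integer(patch_side),
                 stride = as.integer(stride), n = as.integer(n),
                 window = as.integer(window), index_map = index_map),
            class = "dt_field")
}

#' @export
print.dt_field <- function(x, ...) {
  cat(sprintf(
    "dt_field: %d models (grid %d x %d, stride %d), order %d, patch %dx%d, frames %d..%d\n",
    length(x$models), length(x$grid_rows), length(x$grid_cols), x$stride,
    x$n, x$patch_side, x$patch_side, x$window[1], x$window[2]))
  invisible(x)
}

# Pairwise squared Martin distances between model index sets of a field
# (clamped at cap; cap = Inf disables clamping but maps Inf -> Inf).
field_martin_cross <- function(field, idx_a, idx_b,
                               cap = getOption("dyntexseg.distance_cap", 1e6)) {
  .cpp_martin_cross(field$Q, field$n, as.integer(idx_a), as.integer(idx_b),
                    if (is.finite(cap)) cap else -1)
}

# Model index at given pixel positions (matrix with columns row, col).
field_index_at <- function(field, pos) {
  field$index_map[cbind(pos[, 1], pos[, 2])]
}

# Grid position (pixel row/col) of each model index.
field_model_pixels <- function(field) {
  gr <- length(field$grid_rows)
  gcidx <- (seq_along(field$models) - 1L) %/% gr + 1L
  gridx <- (seq_along(field$models) - 1L) %% gr + 1L
  cbind(row = field$grid_rows[gridx], col = field$grid_cols[gcidx])
}
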