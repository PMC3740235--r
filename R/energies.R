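# The four energy terms of the segmentation functional:
#   E = alpha*E_ms + beta*E_ed - gamma*E_sp + zeta*E_top  (reported form)
# E_ms: motion-segmentation likelihood on the DT manifold.
# E_ed: event-detection likelihood on the window-to-window Martin map.
# E_sp: tubular shape prior around a fitted "infinite rectangle".
# E_top: area of the forbidden sign class (phi1<0, phi2>0).

#' Motion-segmentation energy
#'
#' \eqn{E_{ms} = \sum_k \sum_{x \in \Omega_k}
#' [d^2(D_x, \bar D_k)/(2\sigma_k^2) + \log\sigma_k]}: negative
#' log-likelihood of the per-pixel dynamic-texture models under per-region
#' normal statistics on the DT manifold.
#'
#' @param field a `dt_field`.
#' @param labels `H x W` label map (0 background, 1 vessel, 2 thrombus;
#'   label 3/forbidden pixels are scored as background).
#' @param stats named list of `region_stats` for `thrombus`, `vessel`,
#'   `background` (an entry may be `NULL` if its region is empty).
#' @return scalar energy.
#' @export
motion_segmentation_energy <- function(field, labels, stats) {
  .sum_region_nll(labels, stats, function(st) {
    st$d2_grid[field$index_map] / (2 * st$variance) +
      0.5 * log(st$variance)
  })
}

.region_masks <- function(labels) {
  list(thrombus = labels == 2L,
       vessel = labels == 1L,
       background = labels == 0L | labels == 3L)
}

.sum_region_nll <- function(labels, stats, nll_map_fun) {
  if (is.null(stats)) stop_dts("missing_stats", "region statistics missing")
  masks <- .region_masks(labels)
  total <- 0
  for (k in names(masks)) {
    if (!any(masks[[k]])) next
    st <- stats[[k]]
    if (is.null(st)) stop_dts("missing_stats", "no statistics for region '%s'", k)
    e <- nll_map_fun(st)
    total <- total + sum(e[masks[[k]]])
  }
  total
}

#' Event-detection map between two temporal windows
#'
#' Per-pixel squared Martin distance between the model estimated in a
#' reference window (before the thrombus develops) and the model in the
#' current window.  Pixels whose motion pattern changed light up; the
#' static vessel wall and background stay near zero.  Distances are
#' clamped at the configured cap, so degenerate/static models yield large
#' finite values.
#'
#' @param field_t0,field_t `dt_field`s with identical grid geometry and
#'   order.
#' @return object of class `event_map`: list with `delta` (`H x W`
#'   nonnegative matrix) and `delta_grid` (per-model values).
#' @export
event_detection_map <- function(field_t0, field_t) {
  if (field_t0$n != field_t$n ||
      !identical(dim(field_t0$index_map), dim(field_t$index_map)) ||
      !identical(field_t0$grid_rows, field_t$grid_rows) ||
      !identical(field_t0$grid_cols, field_t$grid_cols))
    stop_dts("grid_mismatch", "fields differ in grid geometry or order")
  n <- field_t$n
  cap <- .distance_cap()
  M <- length(field_t$models)
  dg <- numeric(M)
  for (m in seq_len(M)) {
    cols <- ((m - 1L) * n + 1L):(m * n)
    s <- svd(crossprod(field_t0$Q[, cols, drop = FALSE],
                       field_t$Q[, cols, drop = FALSE]))$d
    c2 <- pmin(pmax(s, 0), 1)^2
    d2m <- if (any(c2 < 1e-300)) cap else min(max(0, -sum(log(c2))), cap)
    dg[m] <- if (d2m < 1e-12) 0 else d2m  # numerically identical models
  }
  delta <- matrix(dg[field_t$index_map], field_t$H, field_t$W)
  structure(list(delta = delta, delta_grid = dg), class = "event_map")
}

#' Event-detection energy
#'
#' \eqn{E_{ed} = \sum_k \sum_{x \in \Omega_k}
#' [(\Delta_x - \mu_k)^2/(2\sigma_k^2) + \log\sigma_k]} with per-region
#' normal statistics of the event map.
#'
#' @param map an `event_map` (or plain `H x W` matrix).
#' @param labels `H x W` label map.
#' @param stats named list of `region_stats` carrying `event_mean` and
#'   `event_std`.
#' @return scalar energy.
#' @export
event_detection_energy <- function(map, labels, stats) {
  delta <- if (inherits(map, "event_map")) map$delta else map
  .sum_region_nll(labels, stats, function(st) {
    if (is.na(st$event_mean)) stop_dts("missing_stats", "no event statistics")
    (delta - st$event_mean)^2 / (2 * st$event_std^2) + log(st$event_std)
  })
}

#' Fit an "infinite rectangle" to the vessel region
#'
#' The tubular prior models the vessel as a band of half-width `radius`
#' about a straight centerline.  The centerline is the first principal
#' axis of the region's pixel coordinates through the centroid; the radius
#' is the median perpendicular distance from the region's boundary pixels
#' to the centerline.  For steep centerlines (inclination above
#' `refine_angle` degrees, where the pixel-grid PCA slope quantizes
#' badly), the parameters are refined by Nelder–Mead minimization of the
#' summed squared distances of boundary pixels to the rectangle boundary.
#'
#' @param vessel_mask binary `H x W` mask of the vessel (aortic) region.
#' @param refine_angle inclination threshold (degrees) triggering simplex
#'   refinement; default 30.
#' @return object of class `dts_rectangle`: `slope`, `center` (x, y) =
#'   (col, row), `radius`, `angle` (radians).
#' @export
fit_rectangle <- function(vessel_mask, refine_angle = 30) {
  vessel_mask <- vessel_mask != 0
  pos <- which(vessel_mask, arr.ind = TRUE)
  if (nrow(pos) < 2L) stop_dts("degenerate_mask", "mask has < 2 pixels")
  xy <- cbind(x = pos[, 2], y = pos[, 1])  # x = column, y = row
  ctr <- colMeans(xy)
  cv <- stats::cov(xy)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[1] < 1e-9)
    stop_dts("degenerate_mask", "mask is a single point")
  if (ev$values[2] / ev$values[1] > 1 - 1e-9 && nrow(pos) <= 2L)
    stop_dts("degenerate_mask", "degenerate covariance")
  v <- ev$vectors[, 1]
  if (abs(ev$values[2] - ev$values[1]) < 1e-12 && nrow(pos) < 3L)
    stop_dts("degenerate_mask", "collinear or single-pixel region")
  theta <- atan2(v[2], v[1])                      # centerline inclination
  B <- which(boundary_pixels(vessel_mask), arr.ind = TRUE)
  Bxy <- cbind(B[, 2], B[, 1])
  perp <- function(theta, ctr, pts)
    abs(-sin(theta) * (pts[, 1] - ctr[1]) + cos(theta) * (pts[, 2] - ctr[2]))
  r <- stats::median(perp(theta, ctr, Bxy))
  if (r <= 0) r <- 0.5
  if (abs(theta %% pi) > refine_angle * pi / 180 &&
      abs(theta %% pi) < pi - refine_angle * pi / 180) {
    # refine (angle, normal offset, radius) on the boundary residuals
    obj <- function(par) {
      th <- par[1]; off <- par[2]; rr <- abs(par[3])
      d <- abs(-sin(th) * (Bxy[, 1] - ctr[1]) +
                 cos(th) * (Bxy[, 2] - ctr[2]) - off)
      sum((d - rr)^2)
    }
    op <- stats::optim(c(theta, 0, r), obj, method = "Nelder-Mead",
                       control = list(maxit = 300))
    theta <- op$par[1]
    off <- op$par[2]
    r <- abs(op$par[3])
    ctr <- ctr + off * c(-sin(theta), cos(theta))
  }
  slope <- if (abs(cos(theta)) < 1e-12) Inf else tan(theta)
  structure(list(slope = slope, center = ctr, radius = r, angle = theta),
            class = "dts_rectangle")
}

#' @export
print.dts_rectangle <- function(x, ...) {
  cat(sprintf("rectangle: slope %.3f, center (%.1f, %.1f), radius %.2f px\n",
              x$slope, x$center[1], x$center[2], x$radius))
  invisible(x)
}

#' Binary band mask of a fitted rectangle
#'
#' Pixels within `radius` (perpendicular distance) of the centerline,
#' clipped to the image.
#'
#' @param rect a `dts_rectangle`.
#' @param H,W image dimensions.
#' @return logical `H x W` matrix.
#' @export
rectangle_mask <- function(rect, H, W) {
  cc <- matrix(rep(seq_len(W), each = H), H, W)
  rr <- matrix(rep(seq_len(H), W), H, W)
  d <- abs(-sin(rect$angle) * (cc - rect$center[1]) +
             cos(rect$angle) * (rr - rect$center[2]))
  d <= rect$radius
}

# Distance transform of the rectangle band: 0 inside, Euclidean distance
# to the band outside.
rectangle_distance <- function(rect, H, W) {
  band <- rectangle_mask(rect, H, W)
  if (all(band)) return(matrix(0, H, W))
  if (!any(band)) {  # band off-image: analytic fallback
    cc <- matrix(rep(seq_len(W), each = H), H, W)
    rr <- matrix(rep(seq_len(H), W), H, W)
    d <- abs(-sin(rect$angle) * (cc - rect$center[1]) +
               cos(rect$angle) * (rr - rect$center[2]))
    return(pmax(d - rect$radius, 0))
  }
  as.matrix(EBImage::distmap(1 - band))
}

#' Tubular shape-prior energy
#'
#' \eqn{E_{sp} = \sum_{x \in \Omega_{12}} [\exp(d_R^2(x)/(2\sigma^2)) - 1]}
#' over the thrombus and vessel pixels, where `d_R` is the distance
#' transform of the fitted rectangle band (0 inside).  Pixels far from the
#' band are penalized exponentially.
#'
#' @param labels `H x W` label map.
#' @param rect a `dts_rectangle`.
#' @param sigma_sp shape tolerance (pixels), default 5.
#' @return nonnegative scalar.
#' @export
shape_prior_energy <- function(labels, rect, sigma_sp = 5) {
  stopifnot(sigma_sp > 0)
  H <- nrow(labels); W <- ncol(labels)
  dR <- rectangle_distance(rect, H, W)
  inside <- labels == 1L | labels == 2L
  if (!any(inside)) return(0)
  sum(expm1(pmin(dR[inside]^2 / (2 * sigma_sp^2), 700)))
}

#' Topological energy
#'
#' Area of the forbidden sign class (inside the thrombus contour but
#' outside the vessel contour), measured with the smooth Heaviside:
#' \eqn{E_{top} = \sum_x (1 - H(\phi_1)) H(\phi_2)}.
#'
#' @param phi1,phi2 level-set embedding fields (`H x W`).
#' @param eps_h Heaviside smoothing width (pixels).
#' @return nonnegative scalar.
#' @export
topological_energy <- function(phi1, phi2, eps_h = 1.5) {
  stopifnot(identical(dim(phi1), dim(phi2)))
  sum((1 - smooth_heaviside(phi1, eps_h)) * smooth_heaviside(phi2, eps_h))
}

#' Total segmentation energy
#'
#' Weighted combination `alpha*E_ms + beta*E_ed - gamma*E_sp + zeta*E_top`.
#' Terms given as `NULL`/`NA` count as zero (e.g. no event window).
#'
#' @param e_ms,e_ed,e_sp,e_top the four term values.
#' @param alpha,beta,gamma,zeta weights (defaults 1, 0.5, 0.1, 1.25).
#' @return scalar.
#' @export
total_energy <- function(e_ms, e_ed = 0, e_sp = 0, e_top = 0,
                         alpha = 1, beta = 0.5, gamma = 0.1, zeta = 1.25) {
  z <- function(x) if (is.null(x) || is.na(x)) 0 else x
  alpha * z(e_ms) + beta * z(e_ed) - gamma * z(e_sp) + zeta * z(e_top)
}
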