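# Two-level-set minimizer. The three regions are encoded by the signs of
# two embedding fields: thrombus (phi1<0, phi2<0), vessel (phi1>0,
# phi2<0), background (phi1>0, phi2>0); the fourth sign class (phi1<0,
# phi2>0) is "forbidden" and penalized by the topological energy.
# Minimization alternates (a) seeded resampling of region models and
# refresh of region statistics and of the fitted rectangle with (b) inner
# diffusion-regularized gradient-descent steps on phi1/phi2.

#' Smooth Heaviside and Dirac approximations
#'
#' Compactly supported C1 regularization:
#' \eqn{H(\phi) = \tfrac12 [1 + \phi/\epsilon +
#' \sin(\pi\phi/\epsilon)/\pi]} for \eqn{|\phi| \le \epsilon}, and exactly
#' 0 / 1 outside the band; \eqn{\delta = dH/d\phi =
#' [1 + \cos(\pi\phi/\epsilon)]/(2\epsilon)} on the band, 0 outside.
#' `H(0) = 0.5`, `H` nondecreasing, `H(phi) + H(-phi) = 1`; `delta` is
#' nonnegative, symmetric, and integrates to 1 along any line crossing
#' the zero set.  The exact saturation outside the band matters: with a
#' heavy-tailed regularization, region terms with very unequal variances
#' leak far across the contour and destabilize the competition.
#'
#' @param phi numeric field.
#' @param eps_h smoothing half-width in pixels (default 1.5).
#' @return field of the same shape.
#' @export
smooth_heaviside <- function(phi, eps_h = 1.5) {
  stopifnot(eps_h > 0)
  x <- pmin(pmax(phi / eps_h, -1), 1)
  0.5 * (1 + x + sin(pi * x) / pi)
}

#' @rdname smooth_heaviside
#' @export
smooth_dirac <- function(phi, eps_h = 1.5) {
  stopifnot(eps_h > 0)
  out <- (1 + cos(pi * pmin(pmax(phi / eps_h, -1), 1))) / (2 * eps_h)
  out[abs(phi) > eps_h] <- 0
  out
}

#' Labels from the level-set sign pattern
#'
#' @param phi1,phi2 embedding fields; `phi1 = NULL` selects two-region
#'   mode, where `phi2 < 0` is the inside region.
#' @param inside_label label for the inside region in two-region mode
#'   (default 1, vessel).
#' @return integer `H x W` map: 0 background, 1 vessel, 2 thrombus,
#'   3 forbidden.
#' @export
levelset_labels <- function(phi1, phi2, inside_label = 1L) {
  in2 <- phi2 < 0
  if (is.null(phi1)) {
    lab <- matrix(0L, nrow(phi2), ncol(phi2))
    lab[in2] <- as.integer(inside_label)
    return(lab)
  }
  in1 <- phi1 < 0
  lab <- matrix(0L, nrow(phi2), ncol(phi2))
  lab[in1 & in2] <- 2L
  lab[!in1 & in2] <- 1L
  lab[in1 & !in2] <- 3L
  lab
}

#' Signed distance field of a binary mask
#'
#' Negative inside, positive outside; magnitude is the Euclidean distance
#' to the nearest pixel of the opposite class.  Empty or full masks return
#' a constant field of magnitude `H + W`.
#'
#' @param mask logical/binary `H x W`.
#' @return numeric `H x W`.
#' @export
signed_distance <- function(mask) {
  mask <- mask != 0
  H <- nrow(mask); W <- ncol(mask)
  if (!any(mask)) return(matrix(H + W, H, W))
  if (all(mask)) return(matrix(-(H + W), H, W))
  d_in <- as.matrix(EBImage::distmap(mask))       # dist of inside px to outside
  d_out <- as.matrix(EBImage::distmap(1 - mask))  # dist of outside px to inside
  d_out - d_in
}

#' Gradient-dependent diffusion coefficient
#'
#' \eqn{g = 1 / (1 + |\nabla I|^2 / \eta)} with `eta` the median gradient
#' magnitude of the image on the current zero-level band of the embedding
#' function; slows the contour down on strong edges.  `eta = 0` (flat
#' band) or `eta = Inf` give `g = 1` everywhere.
#'
#' @param image `H x W` intensity image (`NULL` gives `g = 1`).
#' @param contour_band logical mask of the zero-level band.
#' @param eta override for the normalization constant; `NULL` = median on
#'   the band.
#' @return `H x W` field in (0, 1].
#' @export
diffusion_coefficient <- function(image, contour_band = NULL, eta = NULL) {
  if (is.null(image)) return(NULL)
  gm <- .gradient_magnitude(image)
  if (is.null(eta)) {
    if (is.null(contour_band) || !any(contour_band)) return(matrix(1, nrow(image), ncol(image)))
    eta <- stats::median(gm[contour_band])
  }
  if (!is.finite(eta) || eta <= 0) return(matrix(1, nrow(image), ncol(image)))
  1 / (1 + gm^2 / eta)
}

.gradient_magnitude <- function(I) {
  gx <- .central_diff(I, 2L)
  gy <- .central_diff(I, 1L)
  sqrt(gx^2 + gy^2)
}

# central difference along margin (1 rows, 2 cols), replicated edges
.central_diff <- function(f, margin) {
  H <- nrow(f); W <- ncol(f)
  if (margin == 1L) {
    up <- f[c(1, seq_len(H - 1)), , drop = FALSE]
    dn <- f[c(seq_len(H - 1) + 1, H), , drop = FALSE]
  } else {
    up <- f[, c(1, seq_len(W - 1)), drop = FALSE]
    dn <- f[, c(seq_len(W - 1) + 1, W), drop = FALSE]
  }
  (dn - up) / 2
}

# conservative divergence of g * grad(phi), Neumann boundaries
.div_g_grad <- function(phi, g = NULL) {
  H <- nrow(phi); W <- ncol(phi)
  # first differences at half points
  dxp <- cbind(phi[, 2:W] - phi[, 1:(W - 1)], 0)       # phi_{j+1}-phi_j
  dxm <- cbind(0, phi[, 2:W] - phi[, 1:(W - 1)])       # phi_j-phi_{j-1}
  dyp <- rbind(phi[2:H, ] - phi[1:(H - 1), ], 0)
  dym <- rbind(0, phi[2:H, ] - phi[1:(H - 1), ])
  if (is.null(g)) return(dxp - dxm + dyp - dym)
  gxp <- cbind((g[, 2:W] + g[, 1:(W - 1)]) / 2, 0)
  gxm <- cbind(0, (g[, 2:W] + g[, 1:(W - 1)]) / 2)
  gyp <- rbind((g[2:H, ] + g[1:(H - 1), ]) / 2, 0)
  gym <- rbind(0, (g[2:H, ] + g[1:(H - 1), ]) / 2)
  gxp * dxp - gxm * dxm + gyp * dyp - gym * dym
}

#' Rasterize a polygon to a binary mask
#'
#' Even–odd rule at pixel centers.
#'
#' @param vertices numeric matrix, columns (row, col), at least 3 rows.
#' @param H,W image dimensions.
#' @return logical `H x W`.
#' @export
rasterize_polygon <- function(vertices, H, W) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L)
    stop_dts("degenerate_polygon", "polygon needs at least 3 vertices")
  py <- vertices[, 1]; px <- vertices[, 2]
  Y <- matrix(rep(seq_len(H), W), H, W)
  X <- matrix(rep(seq_len(W), each = H), H, W)
  inside <- matrix(FALSE, H, W)
  nv <- length(px)
  j <- nv
  for (i in seq_len(nv)) {
    cross <- ((py[i] > Y) != (py[j] > Y)) &
      (X < (px[j] - px[i]) * (Y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  if (!any(inside))
    stop_dts("degenerate_polygon", "polygon rasterizes to an empty mask")
  inside
}

#' Initialize level-set fields from polygonal contours
#'
#' Each field is the signed distance to the rasterized polygon (negative
#' inside).  The thrombus polygon is clipped to the vessel polygon so the
#' initial thrombus lies inside the vessel.
#'
#' @param vessel_polygon,thrombus_polygon vertex matrices (row, col);
#'   `thrombus_polygon = NULL` gives a two-region initialization
#'   (`phi1 = NULL`).
#' @param shape image dimensions `c(H, W)`.
#' @return list `phi1`, `phi2`.
#' @export
init_from_polygons <- function(vessel_polygon, thrombus_polygon = NULL, shape) {
  H <- shape[1]; W <- shape[2]
  vm <- rasterize_polygon(vessel_polygon, H, W)
  phi2 <- signed_distance(vm)
  phi1 <- NULL
  if (!is.null(thrombus_polygon)) {
    tm <- rasterize_polygon(thrombus_polygon, H, W) & vm
    if (!any(tm))
      stop_dts("degenerate_polygon",
               "thrombus polygon does not intersect the vessel polygon")
    phi1 <- signed_distance(tm)
  }
  list(phi1 = phi1, phi2 = phi2)
}

#' Solver configuration
#'
#' Defaults follow the reference parameterization for real microscopy
#' runs: energy weights `alpha = 1`, `beta = 0.5`, `gamma = 0.1`,
#' `zeta = 1.25`, shape tolerance `sigma_sp = 5` px, model order `n = 15`,
#' window `tau = 75` transitions, 5x5 patches, `n_samples = 60` reference
#' models.  Synthetic experiments use smaller `n`/`tau` matched to the
#' generators (see the vignette).
#'
#' @param alpha,beta,gamma,zeta energy weights.
#' @param sigma_sp shape-prior tolerance (pixels).
#' @param kappa data-term step (fraction of a pixel per inner step; the
#'   data gradient is normalized to unit maximum).
#' @param lambda_d diffusion weight.
#' @param epsilon temporal-regularization weight used by the tracker.
#' @param n,tau,patch_side,stride dynamic-texture field parameters.
#' @param n_samples number of sampled reference models per region.
#' @param mean_mode `"doss"` or `"frechet"`.
#' @param data_mode `"motion"` (dynamic-texture likelihood) or
#'   `"intensity"` (Gaussian intensity likelihood, used for intensity
#'   phantoms).
#' @param eps_h Heaviside/Dirac smoothing width.
#' @param delta_mode `"global"` (default): region forces act on all
#'   pixels (time-rescaled flow, robust to misassigned interior);
#'   `"dirac"`: forces localized to the zero sets by the smooth Dirac.
#' @param eta_mode `"infinite"` (g = 1, synthetic default) or `"image"`
#'   (median-normalized gradient diffusivity).
#' @param max_outer,max_inner,tol outer/inner iteration caps and
#'   label-change convergence threshold.
#' @param nll_cap clamp for per-pixel negative log-likelihood values
#'   entering the flow (keeps the force normalization informative when a
#'   homogeneous region's variance is very small).
#' @param reinit_every re-distance the fields every this many inner steps.
#' @param min_region_px region size below which a contour counts as
#'   vanished.
#' @param seed RNG seed for the per-iteration sample streams.
#' @return named list of class `dts_config`.
#' @export
solver_config <- function(alpha = 1, beta = 0.5, gamma = 0.1, zeta = 1.25,
                          sigma_sp = 5, kappa = 0.5, lambda_d = 0.2,
                          epsilon = 1e-2,
                          n = 15L, tau = 75L, patch_side = 5L, stride = 1L,
                          n_samples = 60L,
                          mean_mode = c("doss", "frechet"),
                          data_mode = c("motion", "intensity"),
                          eps_h = 1.5, delta_mode = c("global", "dirac"),
                          eta_mode = c("infinite", "image"),
                          nll_cap = 50,
                          max_outer = 50L, max_inner = 10L, tol = 1e-3,
                          reinit_every = 10L, min_region_px = 3L,
                          seed = 1L) {
  cfg <- list(alpha = alpha, beta = beta, gamma = gamma, zeta = zeta,
              sigma_sp = sigma_sp, kappa = kappa, lambda_d = lambda_d,
              epsilon = epsilon,
              n = as.integer(n), tau = as.integer(tau),
              patch_side = as.integer(patch_side), stride = as.integer(stride),
              n_samples = as.integer(n_samples),
              mean_mode = match.arg(mean_mode),
              data_mode = match.arg(data_mode),
              eps_h = eps_h, delta_mode = match.arg(delta_mode),
              eta_mode = match.arg(eta_mode), nll_cap = nll_cap,
              max_outer = as.integer(max_outer),
              max_inner = as.integer(max_inner), tol = tol,
              reinit_every = as.integer(reinit_every),
              min_region_px = as.integer(min_region_px),
              seed = as.integer(seed))
  stopifnot(cfg$tau >= cfg$n, cfg$n_samples >= 1L)
  class(cfg) <- "dts_config"
  cfg
}

# ---- internal: data term maps -------------------------------------------

# Per-pixel negative-log-likelihood maps for the three regions; in
# two-region mode only `thrombus`/`background` slots are used for
# inside/outside.  Event maps come tied (vessel+background share one
# normal) for the gradients, untied for energy reporting.
.data_maps <- function(field, intensity, event_map, stats, cfg, two_region) {
  out <- list()
  # negative log-likelihoods clamped at nll_cap: beyond "certainly not this
  # region" the magnitude carries no information, but it would dominate the
  # force normalization when a homogeneous region's variance gets small
  cap <- cfg$nll_cap %||% 50
  if (cfg$data_mode == "intensity") {
    for (k in names(stats)) {
      st <- stats[[k]]
      if (is.null(st)) next
      out[[k]] <- pmin((intensity - st$mean)^2 / (2 * st$sd^2) + log(st$sd),
                       cap)
    }
  } else {
    for (k in names(stats)) {
      st <- stats[[k]]
      if (is.null(st) || !inherits(st, "region_stats")) next
      out[[k]] <- matrix(pmin(st$d2_grid[field$index_map] /
                                (2 * st$variance) +
                                0.5 * log(st$variance), cap),
                         field$H, field$W)
    }
  }
  ev <- NULL
  if (!is.null(event_map)) {
    delta <- event_map$delta
    evm <- function(mu, sd) (delta - mu)^2 / (2 * sd^2) + log(sd)
    ev <- list()
    for (k in names(stats)) {
      st <- stats[[k]]
      if (!is.null(st) && !is.null(st$event_mean) && !is.na(st$event_mean))
        ev[[k]] <- evm(st$event_mean, st$event_std)
    }
    # tied vessel+background normal for the gradient flow
    if (!is.null(stats$tied_event)) {
      te <- stats$tied_event
      ev$tied <- evm(te$mean, te$sd)
    }
  }
  # The event likelihood only discriminates when the thrombus event
  # distribution is separated from the shared vessel/background one; when
  # nothing has changed yet (backward tracking before attachment) both
  # regions fit a near-zero map and the tighter fit would absorb the
  # scene, so the term is switched off for that window.
  ev_degenerate <- FALSE
  if (!is.null(ev) && !is.null(stats$tied_event) &&
      !is.null(stats$thrombus) && !is.na(stats$thrombus$event_mean %||% NA)) {
    sep <- abs(stats$thrombus$event_mean - stats$tied_event$mean)
    ev_degenerate <- sep < stats$tied_event$sd
  }
  list(e = out, ev = ev, ev_degenerate = ev_degenerate)
}

# ---- internal: one gradient-descent step --------------------------------

# Shape-prior force exp(d_R^2/(2 sigma^2)) - 1, clamped like the data
# terms.  The prior acts on the vessel contour (the printed gradient
# carries delta(phi2)); in global delta mode it is therefore windowed to
# the zero-level band of phi2, so its far-field plateau cannot dominate
# the force normalization.
.shape_force <- function(dR2n, phi2, cfg, global_delta) {
  sf <- pmin(expm1(pmin(dR2n, 700)), 2 * (cfg$nll_cap %||% 50))
  if (global_delta)
    sf <- sf * pmin(cfg$eps_h * smooth_dirac(phi2, cfg$eps_h), 1)
  sf
}

# Pointwise soft normalization of the descent force (|v| <= 1): pixels
# with a force at or above the typical scale advance at close to the full
# kappa speed, instead of being scaled by the global force maximum, whose
# wide dynamic range (likelihood ratios vary by orders of magnitude) would
# freeze low-contrast parts of the scene.
.normalize_force <- function(grad) {
  s <- stats::quantile(abs(grad), 0.9, names = FALSE)
  if (!is.finite(s) || s <= 0) s <- max(abs(grad))
  if (!is.finite(s) || s <= 0) return(grad)
  grad / sqrt(grad^2 + (0.2 * s)^2)
}

.flow_step <- function(phi1, phi2, maps, dR2n, cfg, g1, g2, phi2_prev_H = NULL) {
  eps <- cfg$eps_h
  H2 <- smooth_heaviside(phi2, eps)
  # delta_mode "dirac": printed gradient (descent localized to the zero
  # set); "global" (default): the standard time-rescaled variant that
  # drops the Dirac factor so the region-competition force also acts on
  # misassigned interior pixels.
  global_delta <- identical(cfg$delta_mode, "global")
  d2 <- if (global_delta) 1 else smooth_dirac(phi2, eps)
  if (is.null(phi1)) {
    # two-region: inside (phi2<0) vs outside
    e_in <- maps$e$inside; e_out <- maps$e$outside
    grad2 <- matrix(0, nrow(phi2), ncol(phi2))
    if (cfg$alpha != 0 && !is.null(e_in))
      grad2 <- grad2 + cfg$alpha * (e_out - e_in)
    if (cfg$beta != 0 && !is.null(maps$ev$inside))
      grad2 <- grad2 + cfg$beta * (maps$ev$outside - maps$ev$inside)
    if (cfg$gamma != 0 && !is.null(dR2n))
      grad2 <- grad2 - cfg$gamma * .shape_force(dR2n, phi2, cfg, global_delta)
    grad2 <- d2 * grad2
    if (!is.null(phi2_prev_H))
      grad2 <- grad2 + cfg$epsilon * d2 * (1 - 2 * phi2_prev_H)
    grad2 <- .normalize_force(grad2)
    phi2 <- phi2 - cfg$kappa * grad2 + cfg$lambda_d * .div_g_grad(phi2, g2)
    if (!all(is.finite(phi2)))
      stop_dts("numerical_blowup", "phi2 became non-finite")
    return(list(phi1 = NULL, phi2 = phi2))
  }
  H1 <- smooth_heaviside(phi1, eps)
  d1 <- if (global_delta) 1 else smooth_dirac(phi1, eps)
  e1 <- maps$e$thrombus
  e2 <- maps$e$vessel %||% maps$e$background
  e3 <- maps$e$background %||% maps$e$vessel
  z <- matrix(0, nrow(phi2), ncol(phi2))
  g1t <- z; g2t <- z
  if (cfg$alpha != 0 && !is.null(e1)) {
    g1t <- g1t + cfg$alpha * ((1 - H2) * (e2 - e1) + H2 * e3)
    g2t <- g2t + cfg$alpha * (-(1 - H1) * e1 + H1 * (e3 - e2))
  }
  if (cfg$beta != 0 && !is.null(maps$ev) && !isTRUE(maps$ev_degenerate)) {
    ev1 <- maps$ev$thrombus
    ev23 <- if (!is.null(maps$ev$tied)) maps$ev$tied else maps$ev$vessel
    g1t <- g1t + cfg$beta * ((1 - H2) * (ev23 - ev1) + H2 * ev23)
    g2t <- g2t + cfg$beta * (-(1 - H1) * ev1)  # tied: vessel/background cancel
  }
  if (cfg$gamma != 0 && !is.null(dR2n))
    g2t <- g2t - cfg$gamma * .shape_force(dR2n, phi2, cfg, global_delta)
  grad1 <- d1 * g1t - cfg$zeta * d1 * H2
  grad2 <- d2 * g2t + cfg$zeta * d2 * (1 - H1)
  if (!is.null(phi2_prev_H))
    grad2 <- grad2 + cfg$epsilon * d2 * (1 - 2 * phi2_prev_H)
  grad1 <- .normalize_force(grad1)
  grad2 <- .normalize_force(grad2)
  phi1 <- phi1 - cfg$kappa * grad1 + cfg$lambda_d * .div_g_grad(phi1, g1)
  phi2 <- phi2 - cfg$kappa * grad2 + cfg$lambda_d * .div_g_grad(phi2, g2)
  if (!all(is.finite(phi1)) || !all(is.finite(phi2)))
    stop_dts("numerical_blowup", "level-set field became non-finite")
  list(phi1 = phi1, phi2 = phi2)
}

#' One diffusion-regularized gradient-descent step
#'
#' Applies \eqn{\phi_i \leftarrow \phi_i - \kappa \nabla_{\phi_i} E +
#' \lambda \, \mathrm{div}(g_i \nabla \phi_i)} with the full energy
#' gradients (motion, event, shape, topological terms weighted by
#' `alpha`, `beta`, `gamma`, `zeta`).  The data gradient is normalized to
#' unit maximum so `kappa` is a step in pixels.  Exposed mainly for
#' testing; [segment()] drives the full alternation.
#'
#' @param state list with `phi1` (or `NULL`), `phi2`.
#' @param field `dt_field` (or `NULL` in intensity mode).
#' @param event_map `event_map` or `NULL`.
#' @param stats named list of `region_stats` (plus optional `tied_event`).
#' @param rect `dts_rectangle` or `NULL`.
#' @param config `dts_config`.
#' @param intensity intensity image for `data_mode = "intensity"`.
#' @return updated state list.
#' @export
gradient_flow_step <- function(state, field, event_map, stats, rect, config,
                               intensity = NULL) {
  maps <- .data_maps(field, intensity, event_map, stats, config,
                     is.null(state$phi1))
  dR2n <- NULL
  if (config$gamma != 0 && !is.null(rect)) {
    dR <- rectangle_distance(rect, nrow(state$phi2), ncol(state$phi2))
    dR2n <- dR^2 / (2 * config$sigma_sp^2)
  }
  .flow_step(state$phi1, state$phi2, maps, dR2n, config, NULL, NULL)
}

# ---- segment ------------------------------------------------------------

#' Multiphase dynamic-texture segmentation of one temporal window
#'
#' Minimizes the combined energy with two level-set functions (or one, in
#' two-region mode) by alternating until convergence: (a) seeded
#' resampling of region reference models and refresh of region statistics,
#' event statistics and the fitted rectangle from the current labels, and
#' (b) inner diffusion-regularized gradient-descent steps.
#'
#' @param sequence `H x W x T` intensity array (an `H x W` matrix is
#'   treated as a single frame; only valid in intensity mode).
#' @param window frame window `c(first, last)` for the current
#'   dynamic-texture field.
#' @param window_t0 reference window for the event-detection energy, or
#'   `NULL` to disable it (forces `beta = 0`).
#' @param init either a list of polygons
#'   (`list(vessel = , thrombus = )`, vertex matrices (row, col)) or a
#'   list of fields `list(phi1 = , phi2 = )`; `phi1`/`thrombus` absent
#'   selects two-region mode.
#' @param config a [solver_config()].
#' @param inside_label two-region mode: label of the inside region.
#' @param phi2_prev vessel embedding of the already-segmented successor
#'   frame; adds the temporal regularizer
#'   \eqn{\epsilon\,\delta(\phi_2)(1 - 2H(\phi_2^{t+1}))} to the
#'   \eqn{\phi_2} gradient (used by the backward tracker).
#' @return object of class `dts_segmentation`: `labels`, `phi1`, `phi2`,
#'   `stats`, `rect`, `field`, `event_map`, `trace` (per-outer-iteration
#'   energy log), `vanished` (thrombus contour emptied), `converged`.
#' @export
segment <- function(sequence, window = NULL, window_t0 = NULL, init,
                    config = solver_config(), inside_label = 1L,
                    phi2_prev = NULL) {
  if (length(dim(sequence)) == 2L)
    sequence <- array(sequence, c(dim(sequence), 1L))
  dm <- dim(sequence)
  H <- dm[1]; W <- dm[2]; T <- dm[3]
  if (is.null(window)) window <- c(1L, T)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }

  field <- NULL; intensity <- NULL; emap <- NULL
  if (config$data_mode == "motion") {
    field <- compute_dt_field(sequence, window, config$patch_side, config$n,
                              config$stride)
    if (!is.null(window_t0) && config$beta != 0) {
      field_t0 <- compute_dt_field(sequence, window_t0, config$patch_side,
                                   config$n, config$stride)
      emap <- event_detection_map(field_t0, field)
    }
  } else {
    intensity <- .window_mean(sequence, window)
  }

  # initialization
  if (!is.null(init$phi2) || !is.null(init$phi1)) {
    phi1 <- init$phi1; phi2 <- init$phi2
  } else {
    ip <- init_from_polygons(init$vessel, init$thrombus, c(H, W))
    phi1 <- ip$phi1; phi2 <- ip$phi2
  }
  two_region <- is.null(phi1)
  vanished <- two_region

  img_for_g <- if (config$eta_mode == "image") .window_mean(sequence, window) else NULL
  phi2_prev_H <- if (!is.null(phi2_prev))
    smooth_heaviside(phi2_prev, config$eps_h) else NULL
  labels <- levelset_labels(phi1, phi2, inside_label)
  trace <- list()
  converged <- FALSE
  inner_count <- 0L
  stats <- NULL; rect <- NULL

  for (outer in seq_len(max(config$max_outer, 0L))) {
    set.seed(config$seed + outer)
    st <- .refresh_stats(field, intensity, emap, labels, two_region,
                         inside_label, config)
    stats <- st$stats
    if (st$thrombus_vanished && !two_region) {
      two_region <- TRUE; vanished <- TRUE; phi1 <- NULL
      labels <- levelset_labels(NULL, phi2, inside_label)
      st <- .refresh_stats(field, intensity, emap, labels, TRUE,
                           inside_label, config)
      stats <- st$stats
    }
    if (st$inside_vanished) break  # nothing left to segment
    rect <- NULL
    if (config$gamma != 0) {
      vmask <- if (two_region) phi2 < 0 else (phi2 < 0)
      rect <- tryCatch(fit_rectangle(vmask), dyntexseg_error = function(e) NULL)
    }
    dR2n <- NULL
    if (!is.null(rect)) {
      dR <- rectangle_distance(rect, H, W)
      dR2n <- dR^2 / (2 * config$sigma_sp^2)
    }
    maps <- .data_maps(field, intensity, emap, stats, config, two_region)
    g1 <- g2 <- NULL
    if (!is.null(img_for_g)) {
      band2 <- abs(phi2) < 2
      g2 <- diffusion_coefficient(img_for_g, band2)
      if (!two_region) g1 <- diffusion_coefficient(img_for_g, abs(phi1) < 2)
    }
    for (inner in seq_len(config$max_inner)) {
      stp <- .flow_step(phi1, phi2, maps, dR2n, config, g1, g2, phi2_prev_H)
      phi1 <- stp$phi1; phi2 <- stp$phi2
      inner_count <- inner_count + 1L
      if (inner_count %% config$reinit_every == 0L) {
        phi2 <- signed_distance(phi2 < 0)
        if (!two_region) phi1 <- signed_distance(phi1 < 0)
      }
    }
    phi2 <- signed_distance(phi2 < 0)
    if (!two_region) phi1 <- signed_distance(phi1 < 0)
    new_labels <- levelset_labels(phi1, phi2, inside_label)
    flip <- mean(new_labels != labels)
    trace[[outer]] <- data.frame(
      outer = outer, label_change = flip,
      e_ms = .trace_energy(field, intensity, new_labels, stats, config),
      e_ed = if (!is.null(emap))
        tryCatch(event_detection_energy(emap, new_labels, stats),
                 dyntexseg_error = function(e) NA_real_) else NA_real_,
      e_sp = if (!is.null(rect)) shape_prior_energy(new_labels, rect,
                                                    config$sigma_sp) else NA_real_,
      e_top = if (!two_region) topological_energy(phi1, phi2, config$eps_h)
              else NA_real_,
      forbidden_frac = mean(new_labels == 3L),
      thrombus_px = sum(new_labels == 2L),
      vessel_px = sum(new_labels == 1L),
      var_thrombus = if (!is.null(stats$thrombus$variance))
        stats$thrombus$variance else NA_real_,
      var_vessel = if (!is.null(stats$vessel$variance))
        stats$vessel$variance else NA_real_,
      var_background = if (!is.null(stats$background$variance))
        stats$background$variance else NA_real_)
    labels <- new_labels
    if (flip < config$tol) { converged <- TRUE; break }
  }
  if (config$max_outer == 0L) labels <- levelset_labels(phi1, phi2, inside_label)

  structure(list(labels = labels, phi1 = phi1, phi2 = phi2, stats = stats,
                 rect = rect, field = field, event_map = emap,
                 trace = if (length(trace)) do.call(rbind, trace) else NULL,
                 vanished = vanished, converged = converged,
                 config = config),
            class = "dts_segmentation")
}

.window_mean <- function(sequence, window) {
  fr <- window[1]:min(window[2], dim(sequence)[3])
  if (length(fr) == 1L) sequence[, , fr]
  else apply(sequence[, , fr, drop = FALSE], c(1, 2), mean)
}

.trace_energy <- function(field, intensity, labels, stats, cfg) {
  if (cfg$data_mode == "intensity") {
    img <- intensity
    tot <- 0
    masks <- .region_masks(labels)
    for (k in names(masks)) {
      st <- stats[[k]]
      if (is.null(st) || !any(masks[[k]])) next
      tot <- tot + sum(((img - st$mean)^2 / (2 * st$sd^2) +
                          log(st$sd))[masks[[k]]])
    }
    return(tot)
  }
  if (cfg$alpha == 0) return(NA_real_)
  tryCatch(motion_segmentation_energy(field, labels, stats),
           dyntexseg_error = function(e) NA_real_)
}

# Refresh all region statistics from the current labels.
.refresh_stats <- function(field, intensity, emap, labels, two_region,
                           inside_label, cfg) {
  thrombus_vanished <- FALSE; inside_vanished <- FALSE
  stats <- list()
  if (two_region) {
    inmask <- labels == as.integer(inside_label)
    outmask <- !inmask
    if (sum(inmask) < cfg$min_region_px) inside_vanished <- TRUE
    if (inside_vanished || sum(outmask) < cfg$min_region_px)
      return(list(stats = NULL, thrombus_vanished = FALSE,
                  inside_vanished = TRUE))
    stats$inside <- .one_region_stats(field, intensity, emap, inmask,
                                      "inside", cfg)
    stats$outside <- .one_region_stats(field, intensity, emap, outmask,
                                       "outside", cfg)
    return(list(stats = stats, thrombus_vanished = FALSE,
                inside_vanished = FALSE))
  }
  masks <- .region_masks(labels)
  if (sum(masks$thrombus) < cfg$min_region_px) thrombus_vanished <- TRUE
  if (sum(masks$vessel) + sum(masks$thrombus) < cfg$min_region_px)
    inside_vanished <- TRUE
  if (thrombus_vanished || inside_vanished)
    return(list(stats = NULL, thrombus_vanished = thrombus_vanished,
                inside_vanished = inside_vanished))
  for (k in c("thrombus", "vessel", "background")) {
    if (!any(masks[[k]])) { stats[[k]] <- NULL; next }
    stats[[k]] <- .one_region_stats(field, intensity, emap, masks[[k]], k, cfg)
  }
  if (!is.null(emap)) {
    vb <- masks$vessel | masks$background
    ev <- emap$delta[vb]
    stats$tied_event <- list(mean = mean(ev),
                             sd = max(stats::sd(ev), .variance_floor))
  }
  list(stats = stats, thrombus_vanished = FALSE, inside_vanished = FALSE)
}

.one_region_stats <- function(field, intensity, emap, mask, id, cfg) {
  if (cfg$data_mode == "intensity") {
    v <- intensity[mask]
    return(list(region_id = id, mean = mean(v),
                sd = max(stats::sd(v), 1e-3)))
  }
  if (cfg$alpha == 0 && !is.null(emap)) {
    # event-only configuration: the manifold statistics are never used
    ev <- emap$delta[mask]
    return(list(region_id = id, event_mean = mean(ev),
                event_std = max(stats::sd(ev), .variance_floor)))
  }
  region_statistics(field, mask, region_id = id, n_samples = cfg$n_samples,
                    mean_mode = cfg$mean_mode,
                    event_map = if (!is.null(emap)) emap$delta else NULL,
                    patch_side = cfg$patch_side)
}

#' @export
print.dts_segmentation <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:3,
                      labels = c("background", "vessel", "thrombus",
                                 "forbidden")))
  cat("dts_segmentation:", if (x$converged) "converged" else "iteration cap",
      if (x$vanished) "(two-region: thrombus contour vanished)" else "", "\n")
  print(tab)
  invisible(x)
}
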