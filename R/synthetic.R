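# Seeded synthetic-data generators. Every generator is a pure function of
# its seed (global RNG state is saved and restored).
#
# Region textures are built as travelling-wave linear dynamical systems: a
# two-dimensional rotating state z(t) observed through quadrature spatial
# modes cos(k.x), sin(k.x), plus Gaussian state and observation noise.
# Any spatial patch of such a texture sees its signal in the same local
# two-dimensional subspace (the patch restrictions of the quadrature pair),
# so dynamic-texture models estimated anywhere inside a region share an
# observability subspace, while regions with different wave vectors and
# temporal frequencies are far apart in Martin distance — the structure the
# segmentation energies assume.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Random stable linear dynamical system
#'
#' Fixture constructor for patch-level dynamic textures: `A` is a random
#' matrix rescaled to spectral radius 0.95; `C` holds orthonormalized
#' spatially smooth random modes on the `sqrt(p) x sqrt(p)` patch grid
#' (larger `smoothness` = stronger spatial correlation).
#'
#' @param n state order; `p` patch pixel count (square).
#' @param seed RNG seed.
#' @param smoothness Gaussian smoothing radius (pixels) for the modes.
#' @param q_sd,r_sd state / observation noise standard deviations.
#' @param ybar_level mean intensity (default 0.5).
#' @return object of class `lds_spec`: `A`, `C` (p x n orthonormal),
#'   `ybar`, `Q`, `R` (diagonal), `n`, `p`, `seed`.
#' @export
random_stable_lds <- function(n, p, seed = 1L, smoothness = 1.5,
                              q_sd = 0.05, r_sd = 0.01, ybar_level = 0.5) {
  stopifnot(n <= p)
  side <- round(sqrt(p))
  stopifnot(side^2 == p)
  .with_seed(seed, {
    A <- matrix(stats::rnorm(n * n), n, n)
    rho <- max(abs(eigen(A, only.values = TRUE)$values))
    A <- A * (0.95 / rho)
    M <- matrix(stats::rnorm(p * n), p, n)
    if (smoothness > 0) {
      for (j in seq_len(n)) {
        f <- matrix(M[, j], side, side)
        M[, j] <- as.vector(.gauss_smooth(f, smoothness))
      }
    }
    C <- qr.Q(qr(M))[, seq_len(n), drop = FALSE]
    structure(list(A = A, C = C, ybar = rep(ybar_level, p),
                   Q = diag(q_sd^2, n), R = diag(r_sd^2, p),
                   n = as.integer(n), p = as.integer(p),
                   seed = as.integer(seed)),
              class = "lds_spec")
  })
}

.gauss_smooth <- function(f, sigma) {
  r <- max(1L, ceiling(2 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  H <- nrow(f); W <- ncol(f)
  pad <- function(i, nmax) pmin(pmax(i, 1L), nmax)
  out <- matrix(0, H, W)
  for (d in -r:r) out <- out + k[d + r + 1] * f[pad(seq_len(H) + d, H), ]
  f2 <- out; out <- matrix(0, H, W)
  for (d in -r:r) out <- out + k[d + r + 1] * f2[, pad(seq_len(W) + d, W)]
  out
}

#' Simulate a linear dynamical system forward
#'
#' Iterates `z(t+1) = A z(t) + v(t)`, `y(t) = ybar + C z(t) + w(t)` with
#' seeded Gaussian noise; intensities are clipped to `[0, 1]`.
#'
#' @param spec an `lds_spec`.
#' @param T number of frames.
#' @param z0 initial state (default: seeded standard normal draw).
#' @param seed seed for the noise stream (default `spec$seed + 1`).
#' @return `p x T` intensity matrix.
#' @export
simulate_lds <- function(spec, T, z0 = NULL, seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "lds_spec"), T >= 1)
  q_sd <- sqrt(diag(spec$Q)); r_sd <- sqrt(diag(spec$R))
  .with_seed(seed, {
    n <- spec$n; p <- spec$p
    if (is.null(z0)) z0 <- stats::rnorm(n)
    Y <- matrix(0, p, T)
    z <- z0
    for (t in seq_len(T)) {
      Y[, t] <- spec$ybar + spec$C %*% z + stats::rnorm(p, sd = r_sd)
      z <- spec$A %*% z + stats::rnorm(n, sd = q_sd)
    }
    pmin(pmax(Y, 0), 1)
  })
}

# ---- travelling-wave region textures ------------------------------------

#' Travelling-wave texture presets
#'
#' Three qualitative motion regimes: `"thrombus_slow"` (long wavelength,
#' slow rotation, high spectral radius, small state noise),
#' `"blood_fast"` (short wavelength, fast rotation, lower spectral radius,
#' larger state noise), `"background_static"` (near-zero amplitude and
#' noise).  Fields can be overridden.
#'
#' @param preset preset name.
#' @param ... overrides: `wavelength` (px), `orientation` (radians),
#'   `omega` (rad/frame), `rho` (spectral radius), `amp` (intensity
#'   amplitude), `ybar`, `r_sd` (observation noise).
#' @return list of class `texture_spec`.
#' @export
texture_spec <- function(preset = c("thrombus_slow", "blood_fast",
                                    "background_static"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    thrombus_slow = list(wavelength = 9, orientation = 0.5,
                         omega = 0.4, rho = 0.98, amp = 0.22,
                         ybar = 0.55, r_sd = 0.01),
    blood_fast = list(wavelength = 5, orientation = 1.9,
                      omega = 1.1, rho = 0.8, amp = 0.22,
                      ybar = 0.45, r_sd = 0.01),
    background_static = list(wavelength = 18, orientation = 2.6,
                             omega = 0.08, rho = 0.97, amp = 0.08,
                             ybar = 0.5, r_sd = 0.004))
  ov <- list(...)
  base[names(ov)] <- ov
  base$preset <- preset
  class(base) <- "texture_spec"
  base
}

# State trajectory of one wave: rotating pair with spectral radius rho and
# stationary unit scale (q chosen so sd(z) ~ 1).
.wave_states <- function(tex, T) {
  th <- tex$omega
  A <- tex$rho * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  q_sd <- sqrt(max(1 - tex$rho^2, 1e-6))
  phi0 <- stats::runif(1, 0, 2 * pi)
  z <- c(cos(phi0), sin(phi0))
  Z <- matrix(0, 2, T)
  for (t in seq_len(T)) {
    Z[, t] <- z
    z <- A %*% z + stats::rnorm(2, sd = q_sd)
  }
  Z
}

.wave_modes <- function(tex, H, W) {
  kx <- 2 * pi / tex$wavelength * cos(tex$orientation)
  ky <- 2 * pi / tex$wavelength * sin(tex$orientation)
  cc <- matrix(rep(seq_len(W), each = H), H, W)
  rr <- matrix(rep(seq_len(H), W), H, W)
  ph <- kx * cc + ky * rr
  list(cosF = cos(ph), sinF = sin(ph))
}

# Render one texture layer frame by frame: H x W x T array (no clipping).
.render_texture <- function(tex, H, W, T) {
  md <- .wave_modes(tex, H, W)
  Z <- .wave_states(tex, T)
  out <- array(0, c(H, W, T))
  for (t in seq_len(T))
    out[, , t] <- tex$ybar + tex$amp * (md$cosF * Z[1, t] + md$sinF * Z[2, t])
  out
}

#' Scene specification
#'
#' @param labels integer `H x W` ground-truth label map (legend: 0
#'   background, 1 vessel, 2 thrombus).
#' @param textures named list of [texture_spec()]s for `background`,
#'   `vessel`, and (optionally) `thrombus`.
#' @param T number of frames.
#' @param seed RNG seed.
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(labels, textures, T = 75L, seed = 1L) {
  stopifnot(all(labels %in% 0:2), T >= 2)
  structure(list(labels = labels, textures = textures, T = as.integer(T),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Default three-region disk-in-square scene specification
#'
#' A disk (thrombus texture) inside a square (vessel texture) on a
#' near-static background — the synthetic analogue of a developed thrombus
#' inside the aorta.
#'
#' @param H,W,T scene dimensions; `seed` RNG seed.
#' @return a `scene_spec`.
#' @export
disk_square_scene <- function(H = 64L, W = 64L, T = 75L, seed = 1L) {
  labels <- matrix(0L, H, W)
  sq <- round(c(H * 0.17, H * 0.83, W * 0.17, W * 0.83))
  labels[sq[1]:sq[2], sq[3]:sq[4]] <- 1L
  cc <- matrix(rep(seq_len(W), each = H), H, W)
  rr <- matrix(rep(seq_len(H), W), H, W)
  disk <- (rr - H / 2)^2 + (cc - W / 2)^2 <= (min(H, W) * 0.16)^2
  labels[disk] <- 2L
  scene_spec(labels,
             list(background = texture_spec("background_static"),
                  vessel = texture_spec("blood_fast"),
                  thrombus = texture_spec("thrombus_slow")),
             T = T, seed = seed)
}

#' Render a multi-region dynamic-texture scene
#'
#' Each region's pixels follow its own travelling-wave LDS; shared
#' observation noise is added after composition and intensities are
#' clipped to `[0, 1]`.
#'
#' @param spec a `scene_spec`.
#' @return list `sequence` (`H x W x T`), `labels` (ground truth).
#' @export
make_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- nrow(spec$labels); W <- ncol(spec$labels); T <- spec$T
  .with_seed(spec$seed, {
    seq_out <- array(0, c(H, W, T))
    lab_of <- c(background = 0L, vessel = 1L, thrombus = 2L)
    r_sd <- 0
    for (k in names(spec$textures)) {
      tex <- spec$textures[[k]]
      mask <- spec$labels == lab_of[[k]]
      if (!any(mask)) next
      layer <- .render_texture(tex, H, W, T)
      for (t in seq_len(T)) {
        fr <- seq_out[, , t]
        fr[mask] <- layer[, , t][mask]
        seq_out[, , t] <- fr
      }
      r_sd <- max(r_sd, tex$r_sd)
    }
    if (r_sd > 0)
      seq_out <- seq_out + array(stats::rnorm(length(seq_out), sd = r_sd),
                                 dim(seq_out))
    list(sequence = pmin(pmax(seq_out, 0), 1), labels = spec$labels)
  })
}

#' Temporally shifted scene pair with a changed foreground
#'
#' Two windows of a two-region scene: the background texture keeps its
#' parameters (fresh noise and phase draws, so intensities differ while
#' the statistics match); the foreground region's wave is replaced in the
#' second window.  Models the appearance of a new motion pattern (the
#' thrombus) at fixed shape.
#'
#' @param fg_mask logical `H x W` foreground mask (default: centered disk
#'   in a 64 x 64 frame).
#' @param T frames per window; `seed` RNG seed.
#' @param change replace the foreground texture in window t
#'   (`TRUE`, default); `FALSE` gives a zero-change control pair.
#' @return list `sequence_t0`, `sequence_t`, `fg_mask`.
#' @export
make_event_pair <- function(fg_mask = NULL, T = 60L, seed = 1L,
                            change = TRUE) {
  if (is.null(fg_mask)) {
    H <- 64L; W <- 64L
    cc <- matrix(rep(seq_len(W), each = H), H, W)
    rr <- matrix(rep(seq_len(H), W), H, W)
    fg_mask <- (rr - H / 2)^2 + (cc - W / 2)^2 <= 12^2
  }
  H <- nrow(fg_mask); W <- ncol(fg_mask)
  labels <- matrix(0L, H, W); labels[fg_mask] <- 2L
  bg <- texture_spec("blood_fast", wavelength = 6, orientation = 0.4,
                     omega = 0.9, ybar = 0.5)
  fg0 <- texture_spec("blood_fast", wavelength = 5, orientation = 2.1,
                      omega = 1.2, ybar = 0.5)
  fg1 <- if (change)
    texture_spec("thrombus_slow", wavelength = 9, orientation = 5 * pi / 6,
                 omega = 0.2, ybar = 0.5)
  else fg0
  s0 <- make_scene(scene_spec(labels, list(background = bg, thrombus = fg0),
                              T = T, seed = seed))
  s1 <- make_scene(scene_spec(labels, list(background = bg, thrombus = fg1),
                              T = T, seed = seed + 7919L))
  list(sequence_t0 = s0$sequence, sequence_t = s1$sequence,
       fg_mask = fg_mask)
}

#' Intensity-based vessel phantom with collateral branches
#'
#' A bright near-horizontal band (the aorta) with thin bright collateral
#' branches leaving it, on a dark background, plus Gaussian noise.  The
#' intensity contrast (not motion) carries the segmentation cue; used to
#' exercise the tubular shape prior.
#'
#' @param H,W image dimensions.
#' @param radius tube half-width (px).
#' @param n_collaterals number of branches.
#' @param collateral_width branch half-width (px).
#' @param intensity,background tube / background gray levels.
#' @param noise_sd additive noise.
#' @param seed RNG seed.
#' @return list `image` (`H x W`), `tube_mask`, `full_mask`
#'   (tube + collaterals), `collateral_mask`.
#' @export
make_vessel_phantom <- function(H = 96L, W = 128L, radius = 10,
                                n_collaterals = 3L, collateral_width = 2,
                                intensity = 0.8, background = 0.2,
                                noise_sd = 0.04, seed = 1L) {
  .with_seed(seed, {
    cy <- H / 2
    tube <- matrix(FALSE, H, W)
    rr <- matrix(rep(seq_len(H), W), H, W)
    tube[abs(rr - cy) <= radius] <- TRUE
    coll <- matrix(FALSE, H, W)
    xs <- round(seq(W * 0.2, W * 0.8, length.out = n_collaterals))
    for (i in seq_len(n_collaterals)) {
      x0 <- xs[i]
      updown <- if (i %% 2L == 0L) 1 else -1
      len <- round(H * 0.3)
      drift <- stats::runif(1, -0.4, 0.4)
      for (s in seq_len(len)) {
        y <- round(cy + updown * (radius + s))
        x <- round(x0 + drift * s)
        if (y < 1 || y > H) break
        xr <- max(1, x - collateral_width):min(W, x + collateral_width)
        coll[y, xr] <- TRUE
      }
    }
    coll <- coll & !tube
    img <- matrix(background, H, W)
    img[tube | coll] <- intensity
    img <- img + matrix(stats::rnorm(H * W, sd = noise_sd), H, W)
    list(image = pmin(pmax(img, 0), 1), tube_mask = tube,
         full_mask = tube | coll, collateral_mask = coll)
  })
}

#' Growing-plug sequence with known TTA and TSA
#'
#' A horizontal vessel band (fast texture) on a near-static background;
#' from `onset` on, a plug with a slow texture grows inside the vessel
#' with linearly increasing area, up to a radius bounded by the band.
#' Ground-truth per-frame labels and TSA series are returned.
#'
#' @param H,W,T sequence dimensions.
#' @param onset first frame of plug growth.
#' @param growth_rate plug area increase (px^2/frame).
#' @param band_halfwidth vessel half-width (px).
#' @param seed RNG seed.
#' @return list `sequence`, `labels` (list of per-frame maps),
#'   `tsa_true` (px per frame), `onset`, `tta_true_frame`.
#' @export
make_growing_plug_sequence <- function(H = 96L, W = 128L, T = 300L,
                                       onset = 120L, growth_rate = 8,
                                       band_halfwidth = 16, seed = 1L) {
  stopifnot(onset < T)
  .with_seed(seed, {
    cy <- H / 2; cx <- W / 2
    rr <- matrix(rep(seq_len(H), W), H, W)
    cc <- matrix(rep(seq_len(W), each = H), H, W)
    band <- abs(rr - cy) <= band_halfwidth
    bg <- texture_spec("background_static")
    ves <- texture_spec("blood_fast")
    thr <- texture_spec("thrombus_slow")
    lay_bg <- .render_texture(bg, H, W, T)
    lay_v <- .render_texture(ves, H, W, T)
    lay_t <- .render_texture(thr, H, W, T)
    rmax <- band_halfwidth - 2
    d2 <- (rr - cy)^2 + (cc - cx)^2
    seq_out <- array(0, c(H, W, T))
    labels <- vector("list", T)
    tsa <- numeric(T)
    for (t in seq_len(T)) {
      fr <- lay_bg[, , t]
      fr[band] <- lay_v[, , t][band]
      lab <- matrix(0L, H, W); lab[band] <- 1L
      if (t >= onset) {
        area <- growth_rate * (t - onset + 1)
        r <- min(sqrt(area / pi), rmax)
        plug <- d2 <= r^2 & band
        fr[plug] <- lay_t[, , t][plug]
        lab[plug] <- 2L
        tsa[t] <- sum(plug)
      }
      seq_out[, , t] <- fr
      labels[[t]] <- lab
    }
    seq_out <- seq_out + array(stats::rnorm(length(seq_out), sd = 0.008),
                               dim(seq_out))
    list(sequence = pmin(pmax(seq_out, 0), 1), labels = labels,
         tsa_true = tsa, onset = as.integer(onset),
         tta_true_frame = as.integer(onset))
  })
}
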