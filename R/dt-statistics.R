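# Approximate normal statistics on the manifold of dynamic-texture models.
# The intrinsic mean/variance are intractable for LDS models, so the region
# statistics use (a) a sampled Fréchet mean found by exhaustive search over
# the models observed in the region, or (b) the Doss surrogate, which
# replaces the squared distance to the mean by the weighted mean of squared
# distances to a random sample of region models.

.distance_cap <- function() getOption("dyntexseg.distance_cap", 1e6)
.variance_floor <- 1e-6

# In-region pixels with a 4-neighbour outside the region (image edges do
# not count as boundary: the object continues there).
boundary_pixels <- function(mask) {
  mask <- mask != 0
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(TRUE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  inner <- pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)] &
    pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)]
  mask & !inner
}

# Euclidean distance from every pixel to the nearest boundary pixel of the
# region (0 on the boundary itself). Returns an H x W matrix.
.dist_to_region_boundary <- function(mask) {
  B <- boundary_pixels(mask)
  if (!any(B)) return(matrix(Inf, nrow(mask), ncol(mask)))
  as.matrix(EBImage::distmap(1 - B))
}

#' Boundary-confidence weights for region samples
#'
#' Models estimated from patches that straddle a region boundary mix two
#' motion patterns and are unreliable; samples are therefore weighted by
#' their squared distance to the region boundary, capped at the squared
#' patch side: \eqn{w(y) = \min(d_S(y, \Omega_k)^2, s^2)}, then normalized
#' to sum to one.
#'
#' @param region_mask binary `H x W` matrix.
#' @param sample_positions integer matrix with columns (row, col), inside
#'   the region.
#' @param patch_side cap parameter `s` (pixels), default 5.
#' @param normalize return normalized weights (default) or raw capped
#'   squared distances.
#' @return numeric vector, one weight per sample (sums to 1 when
#'   normalized; uniform fallback when every raw weight is zero).
#' @export
confidence_weights <- function(region_mask, sample_positions, patch_side = 5,
                               normalize = TRUE) {
  region_mask <- region_mask != 0
  if (!any(region_mask)) stop_dts("empty_region", "region mask is empty")
  sample_positions <- .as_pos(sample_positions)
  dmap <- .dist_to_region_boundary(region_mask)
  d <- dmap[cbind(sample_positions[, 1], sample_positions[, 2])]
  raw <- pmin(d^2, patch_side^2)
  if (!normalize) return(raw)
  s <- sum(raw)
  if (s <= 0) rep(1 / length(raw), length(raw)) else raw / s
}

.as_pos <- function(pos) {
  pos <- as.matrix(pos)
  storage.mode(pos) <- "integer"
  if (ncol(pos) != 2L) stop_dts("degenerate_input", "positions need 2 columns")
  pos
}

#' Sampled Fréchet mean of region dynamic-texture models
#'
#' Exhaustive search over candidate models for the one minimizing the
#' weighted sum of squared Martin distances to the sampled region models.
#' Ties are broken deterministically towards the lowest linear pixel index
#' (column-major) of the candidate grid position.
#'
#' @param field a `dt_field`.
#' @param sample_positions pixel positions (matrix row, col) of the sampled
#'   region models.
#' @param weights nonnegative sample weights (normalized internally).
#' @param candidate_positions candidate pixel positions; default every
#'   modelled grid position.
#' @return the winning `dt_model`, with attributes `index` (model index in
#'   the field) and `objective` (minimized weighted sum).
#' @export
frechet_mean <- function(field, sample_positions, weights = NULL,
                         candidate_positions = NULL) {
  sample_positions <- .as_pos(sample_positions)
  if (nrow(sample_positions) == 0L)
    stop_dts("empty_samples", "no sample positions")
  if (is.null(weights)) weights <- rep(1, nrow(sample_positions))
  weights <- weights / sum(weights)
  si <- field_index_at(field, sample_positions)
  if (is.null(candidate_positions)) {
    ci <- seq_along(field$models)
  } else {
    ci <- unique(field_index_at(field, .as_pos(candidate_positions)))
  }
  D2 <- field_martin_cross(field, ci, si)
  obj <- as.vector(D2 %*% weights)
  # tie-break: lowest linear (column-major) pixel index of the grid
  # position; objectives within 1e-12 relative tolerance count as tied
  mp <- field_model_pixels(field)[ci, , drop = FALSE]
  lin <- (mp[, 2] - 1) * field$H + mp[, 1]
  o_min <- min(obj)
  tied <- which(obj <= o_min + 1e-12 * (1 + abs(o_min)))
  best <- tied[which.min(lin[tied])]
  out <- field$models[[ci[best]]]
  attr(out, "index") <- ci[best]
  attr(out, "objective") <- obj[best]
  out
}

#' Doss surrogate for the squared distance to the region mean
#'
#' Upper-bound surrogate replacing the squared Martin distance from a model
#' to the (intractable) region mean by the weighted mean of squared
#' distances to sampled region models:
#' \eqn{d^2(x, \bar D) \approx \sum_y w(y) d_M^2(D_x, D_y)}.
#' More robust to estimation noise than the sampled Fréchet mean because
#' independent distance noise averages out.
#'
#' @param x_model a `dt_model`.
#' @param field,sample_positions,weights as in [frechet_mean()].
#' @return nonnegative scalar; infinite distances are clamped at the
#'   configured cap (`options(dyntexseg.distance_cap = )`, default 1e6).
#' @export
doss_sq_distance <- function(x_model, field, sample_positions, weights = NULL) {
  sample_positions <- .as_pos(sample_positions)
  if (nrow(sample_positions) == 0L)
    stop_dts("empty_samples", "no sample positions")
  if (is.null(weights)) weights <- rep(1, nrow(sample_positions))
  weights <- weights / sum(weights)
  si <- field_index_at(field, sample_positions)
  cap <- .distance_cap()
  d2 <- vapply(si, function(i) {
    min(martin_distance(x_model, field$models[[i]]), cap)
  }, numeric(1))
  sum(weights * d2)
}

# Squared distance from every model in the field to the region mean:
# Doss mode -> weighted row sums of the model x sample distance matrix;
# Fréchet mode -> distances to the single mean model.
.d2_grid <- function(field, mode, sample_idx, sample_w, mean_idx) {
  all_idx <- seq_along(field$models)
  if (mode == "doss") {
    D2 <- field_martin_cross(field, all_idx, sample_idx)
    as.vector(D2 %*% sample_w)
  } else {
    as.vector(field_martin_cross(field, all_idx, mean_idx))
  }
}

#' Variance of the dynamic-texture models of a region
#'
#' \eqn{\sigma^2 = \sum_{x \in \Omega_k} p(D_x) d^2(D_x, \bar D)} with
#' `p` the normalized boundary-confidence weights over the region pixels
#' and `d^2` either the distance to a Fréchet mean or the Doss surrogate.
#' Floored at 1e-6 so the log-likelihood stays finite for
#' motion-homogeneous regions.
#'
#' @param field a `dt_field`.
#' @param region_mask binary `H x W`.
#' @param mean a `dt_model` (Fréchet mode), or `NULL` to use `samples`.
#' @param samples,sample_weights Doss-mode sample positions and weights.
#' @param patch_side confidence-weight cap parameter.
#' @return nonnegative scalar.
#' @export
region_variance <- function(field, region_mask, mean = NULL, samples = NULL,
                            sample_weights = NULL, patch_side = 5) {
  region_mask <- region_mask != 0
  if (!any(region_mask)) stop_dts("empty_region", "region mask is empty")
  pos <- which(region_mask, arr.ind = TRUE)
  pw <- confidence_weights(region_mask, pos, patch_side)
  idx <- field_index_at(field, pos)
  if (!is.null(mean)) {
    mi <- attr(mean, "index")
    if (is.null(mi)) {  # model not from this field: direct distances
      cap <- .distance_cap()
      uidx <- unique(idx)
      d2u <- vapply(uidx, function(i)
        min(martin_distance(mean, field$models[[i]]), cap), numeric(1))
      d2 <- d2u[match(idx, uidx)]
    } else {
      d2g <- .d2_grid(field, "frechet", NULL, NULL, mi)
      d2 <- d2g[idx]
    }
  } else {
    if (is.null(samples)) stop_dts("empty_samples", "need mean or samples")
    samples <- .as_pos(samples)
    if (is.null(sample_weights)) sample_weights <- rep(1, nrow(samples))
    sample_weights <- sample_weights / sum(sample_weights)
    si <- field_index_at(field, samples)
    d2g <- .d2_grid(field, "doss", si, sample_weights, NULL)
    d2 <- d2g[idx]
  }
  max(sum(pw * d2), .variance_floor)
}

#' Region statistics for one temporal window
#'
#' Samples `n_samples` modelled positions inside the region (uses the
#' caller's RNG stream: seed upstream for reproducibility), computes
#' boundary-confidence weights, the region mean (sampled Fréchet or Doss
#' surrogate), the region variance, the per-model squared-distance grid
#' used by the energies, and — when an event map is supplied — the normal
#' statistics of the event-detection values in the region.
#'
#' @param field a `dt_field`.
#' @param region_mask binary `H x W`.
#' @param region_id one of `"thrombus"`, `"vessel"`, `"background"`.
#' @param n_samples number of sampled reference models.
#' @param mean_mode `"doss"` (default) or `"frechet"`.
#' @param event_map optional `H x W` event-detection map.
#' @param patch_side confidence cap parameter.
#' @return object of class `region_stats`.
#' @export
region_statistics <- function(field, region_mask, region_id = "thrombus",
                              n_samples = 60L, mean_mode = c("doss", "frechet"),
                              event_map = NULL, patch_side = 5) {
  mean_mode <- match.arg(mean_mode)
  region_mask <- region_mask != 0
  if (!any(region_mask)) stop_dts("empty_region", "region '%s' is empty", region_id)
  # modelled grid positions inside the region
  mp <- field_model_pixels(field)
  inreg <- region_mask[cbind(mp[, 1], mp[, 2])]
  cand <- which(inreg)
  if (length(cand) == 0L) {
    # region thinner than the model grid: fall back to nearest models of
    # the region pixels
    cand <- unique(field_index_at(field, which(region_mask, arr.ind = TRUE)))
  }
  take <- if (length(cand) > n_samples) sample(cand, n_samples) else cand
  spos <- mp[take, , drop = FALSE]
  sw <- confidence_weights(region_mask, .clamp_pos(spos, region_mask),
                           patch_side)
  fm <- NULL; mi <- NULL
  if (mean_mode == "frechet") {
    fm <- frechet_mean(field, spos, sw,
                       candidate_positions = mp[cand, , drop = FALSE])
    mi <- attr(fm, "index")
  }
  d2_grid <- .d2_grid(field, mean_mode, take, sw, mi)
  # variance over region pixels with normalized confidence weights
  pos <- which(region_mask, arr.ind = TRUE)
  pw <- confidence_weights(region_mask, pos, patch_side)
  d2 <- d2_grid[field_index_at(field, pos)]
  variance <- max(sum(pw * d2), .variance_floor)
  ev_mean <- NA_real_; ev_sd <- NA_real_
  if (!is.null(event_map)) {
    ev <- event_map[region_mask]
    ev_mean <- mean(ev)
    ev_sd <- max(stats::sd(ev), .variance_floor)
    if (is.na(ev_sd)) ev_sd <- .variance_floor
  }
  structure(list(region_id = region_id, mean_mode = mean_mode,
                 frechet_mean = fm, sample_positions = spos,
                 sample_weights = sw, variance = variance,
                 event_mean = ev_mean, event_std = ev_sd,
                 d2_grid = d2_grid),
            class = "region_stats")
}

# samples can sit at clamped grid positions just outside a thin region;
# snap them to the nearest region pixel for the boundary-distance lookup
.clamp_pos <- function(pos, mask) {
  ok <- mask[cbind(pos[, 1], pos[, 2])]
  if (all(ok)) return(pos)
  reg <- which(mask, arr.ind = TRUE)
  for (i in which(!ok)) {
    d <- (reg[, 1] - pos[i, 1])^2 + (reg[, 2] - pos[i, 2])^2
    pos[i, ] <- reg[which.min(d), ]
  }
  pos
}

#' Negative log-likelihood contribution of one model in a region
#'
#' \eqn{d^2(x)/(2\sigma^2) + \log\sigma} where `d^2` is the squared Martin
#' distance to the region's Fréchet mean or the Doss surrogate, per the
#' statistics object's mode.
#'
#' @param x_model a `dt_model`.
#' @param stats a `region_stats` object.
#' @param field the `dt_field` the statistics were computed on.
#' @return scalar.
#' @export
region_log_likelihood <- function(x_model, stats, field) {
  stopifnot(inherits(stats, "region_stats"))
  d2 <- if (stats$mean_mode == "frechet") {
    min(martin_distance(x_model, stats$frechet_mean), .distance_cap())
  } else {
    doss_sq_distance(x_model, field, stats$sample_positions,
                     stats$sample_weights)
  }
  d2 / (2 * stats$variance) + 0.5 * log(stats$variance)
}
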