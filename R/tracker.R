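# Backward tracking: segment the last temporal window from a polygon
# initialization (the thrombus has developed there), then propagate the
# level-set fields backwards, one active frame every `decimation` frames,
# with a small temporal regularizer keeping the vessel contour close to
# its successor. Skipped frames are filled by shape-based interpolation.

#' Track thrombus and vessel backward through a sequence
#'
#' @param sequence `H x W x T` intensity array.
#' @param init polygon list (`list(vessel=, thrombus=)`) used at the last
#'   active frame.
#' @param config a [solver_config()]; `config$epsilon` weights the
#'   temporal vessel regularizer.
#' @param decimation active segmentation every this many frames
#'   (default 10, emulating a 25 to 2.5 fps reduction).
#' @param frame_rate frames per second (default 25).
#' @param pixel_size physical pixel size `c(dx, dy)` in micrometers
#'   (default `c(0.55, 0.56)`).
#' @param min_area thrombus-area threshold (px) operationalizing
#'   "attachment" for the TTA (default 5).
#' @param max_outer_warm outer-iteration cap for warm-started frames.
#' @param window_lead number of frames of the temporal window ahead of
#'   the active frame (default `tau %/% 2`, a centered window; smaller
#'   values reduce the anticipation of a growing thrombus).
#' @return object of class `dts_track`: `frame_labels` (list, one `H x W`
#'   map per frame), `active_frames`, `measures` (data.frame: frame,
#'   time_s, tsa_px, tsa_um2, vessel_px, active), `tta_s`, `meta`.
#' @export
track <- function(sequence, init, config = solver_config(),
                  decimation = 10L, frame_rate = 25, pixel_size = c(0.55, 0.56),
                  min_area = 5L, max_outer_warm = 8L,
                  window_lead = NULL) {
  dm <- dim(sequence)
  stopifnot(length(dm) == 3L)
  H <- dm[1]; W <- dm[2]; T <- dm[3]
  tau <- config$tau
  if (T <= tau + 1L)
    stop_dts("sequence_too_short", "need more than tau+1 = %d frames, got %d",
             tau + 1L, T)
  lead <- if (is.null(window_lead)) tau %/% 2L else as.integer(window_lead)
  stopifnot(lead >= 0L, lead <= tau)
  t_min <- (tau - lead) + 1L
  t_max <- T - lead
  active <- rev(seq(t_max, t_min, by = -decimation))
  win_of <- function(t) c(t - (tau - lead), t + lead)
  window_t0 <- win_of(active[1])

  seg_labels <- vector("list", length(active))
  prev <- NULL
  two_region <- FALSE
  for (i in rev(seq_along(active))) {
    t <- active[i]
    if (is.null(prev)) {
      res <- segment(sequence, win_of(t), window_t0 = window_t0,
                     init = init, config = config)
    } else {
      cfg <- config
      cfg$max_outer <- as.integer(max_outer_warm)
      init_phis <- if (two_region) list(phi1 = NULL, phi2 = prev$phi2)
                   else list(phi1 = prev$phi1, phi2 = prev$phi2)
      res <- segment(sequence, win_of(t), window_t0 = window_t0,
                     init = init_phis, config = cfg,
                     phi2_prev = prev$phi2)
    }
    if (res$vanished) two_region <- TRUE
    if (!two_region && config$beta != 0 && .no_attachment_evidence(res)) {
      # pre-attachment regime: the thrombus event distribution is
      # indistinguishable from the vessel/background one, so the window
      # holds no evidence of changed motion -- drop the thrombus contour
      res$labels[res$labels == 2L] <- 1L
      two_region <- TRUE
    }
    seg_labels[[i]] <- res$labels
    prev <- res
  }

  frame_labels <- .interpolate_frames(seg_labels, active, T, H, W)
  tsa_px <- vapply(frame_labels, function(l) sum(l == 2L), numeric(1))
  vessel_px <- vapply(frame_labels, function(l) sum(l == 1L | l == 2L),
                      numeric(1))
  um2 <- prod(pixel_size)
  measures <- data.frame(frame = seq_len(T),
                         time_s = (seq_len(T) - 1) / frame_rate,
                         tsa_px = tsa_px, tsa_um2 = tsa_px * um2,
                         vessel_px = vessel_px,
                         active = seq_len(T) %in% active)
  structure(list(frame_labels = frame_labels, active_frames = active,
                 measures = measures,
                 tta_s = compute_tta(tsa_px, frame_rate, min_area),
                 meta = list(frame_rate = frame_rate, pixel_size = pixel_size,
                             decimation = decimation, min_area = min_area,
                             config = config)),
            class = "dts_track")
}

# Event-evidence test for backward tracking: TRUE when the thrombus
# region's event mean is within one standard deviation of the tied
# vessel/background event distribution.
.no_attachment_evidence <- function(res) {
  st <- res$stats
  if (is.null(st$thrombus) || is.null(st$tied_event)) return(FALSE)
  mu1 <- st$thrombus$event_mean
  if (is.null(mu1) || is.na(mu1)) return(FALSE)
  abs(mu1 - st$tied_event$mean) < st$tied_event$sd
}

# fill non-active frames by shape interpolation between the flanking
# active segmentations; extend endpoints by copying
.interpolate_frames <- function(seg_labels, active, T, H, W) {
  out <- vector("list", T)
  for (i in seq_along(active)) out[[active[i]]] <- seg_labels[[i]]
  for (i in seq_len(length(active) - 1L)) {
    ta <- active[i]; tb <- active[i + 1L]
    if (tb - ta <= 1L) next
    la <- seg_labels[[i]]; lb <- seg_labels[[i + 1L]]
    va <- la == 1L | la == 2L; vb <- lb == 1L | lb == 2L
    tha <- la == 2L; thb <- lb == 2L
    for (t in (ta + 1L):(tb - 1L)) {
      u <- (t - ta) / (tb - ta)
      v <- shape_interpolate(va, vb, u)
      th <- shape_interpolate(tha, thb, u) & v
      lab <- matrix(0L, H, W)
      lab[v] <- 1L
      lab[th] <- 2L
      out[[t]] <- lab
    }
  }
  if (active[1] > 1L)
    for (t in seq_len(active[1] - 1L)) out[[t]] <- out[[active[1]]]
  la <- active[length(active)]
  if (la < T) for (t in (la + 1L):T) out[[t]] <- out[[la]]
  out
}

#' Shape-based interpolation between two masks
#'
#' Thresholds the linear blend of the two signed distance fields:
#' `mask(u) = { (1-u) sdf(a) + u sdf(b) < 0 }`.
#'
#' @param mask_a,mask_b binary masks of equal shape.
#' @param u blend fraction in `[0, 1]` (`0` returns `mask_a`).
#' @return logical mask.
#' @export
shape_interpolate <- function(mask_a, mask_b, u) {
  stopifnot(identical(dim(mask_a), dim(mask_b)), u >= 0, u <= 1)
  if (u == 0) return(mask_a != 0)
  if (u == 1) return(mask_b != 0)
  (1 - u) * signed_distance(mask_a) + u * signed_distance(mask_b) < 0
}

#' Time to attachment
#'
#' First frame whose thrombus area reaches `min_area` pixels, expressed in
#' seconds with frame numbers counted from zero (`NA` if never reached).
#' The area threshold operationalizes "attachment of the first blood
#' cell"; its sensitivity is documented in the examples.
#'
#' @param frame_labels list of label maps, or a numeric vector of
#'   per-frame thrombus areas.
#' @param frame_rate frames per second.
#' @param min_area area threshold in pixels (default 5).
#' @return seconds (scalar) or `NA_real_`.
#' @export
compute_tta <- function(frame_labels, frame_rate, min_area = 5L) {
  stopifnot(frame_rate > 0)
  areas <- if (is.numeric(frame_labels)) frame_labels
           else vapply(frame_labels, function(l) sum(l == 2L), numeric(1))
  hit <- which(areas >= min_area)
  if (length(hit) == 0L) return(NA_real_)
  (hit[1] - 1) / frame_rate
}

#' Thrombus surface area series
#'
#' Per-frame thrombus pixel counts and physical areas.
#'
#' @param frame_labels list of label maps (2 = thrombus).
#' @param pixel_size `c(dx, dy)` in micrometers per pixel.
#' @return data.frame with `frame`, `tsa_px`, `tsa_um2`.
#' @export
compute_tsa <- function(frame_labels, pixel_size = c(0.55, 0.56)) {
  px <- vapply(frame_labels, function(l) sum(l == 2L), numeric(1))
  data.frame(frame = seq_along(px), tsa_px = px,
             tsa_um2 = px * prod(pixel_size))
}

#' Normalized sum of absolute differences between two area series
#'
#' \eqn{\sum_t |est(t) - gt(t)| / \sum_t gt(t)}; 0 means perfect recovery,
#' values above 1 mean an error larger than the quantity itself.
#'
#' @param tsa_est,tsa_gt numeric series of equal length.
#' @return nonnegative scalar.
#' @export
normalized_sad <- function(tsa_est, tsa_gt) {
  if (length(tsa_est) != length(tsa_gt))
    stop_dts("shape_mismatch", "series lengths differ (%d vs %d)",
             length(tsa_est), length(tsa_gt))
  s <- sum(tsa_gt)
  if (s <= 0) stop_dts("zero_reference", "reference series sums to zero")
  sum(abs(tsa_est - tsa_gt)) / s
}

#' @export
print.dts_track <- function(x, ...) {
  cat(sprintf("dts_track: %d frames, %d active, TTA = %s s\n",
              nrow(x$measures), length(x$active_frames),
              if (is.na(x$tta_s)) "undefined" else format(x$tta_s)))
  invisible(x)
}

#' Plot the thrombus-area series of a track result
#'
#' @param x a `dts_track`.
#' @param truth optional true TSA series (px) for overlay.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dts_track <- function(x, truth = NULL, ...) {
  m <- x$measures
  graphics::plot(m$time_s, m$tsa_px, type = "l", xlab = "time (s)",
                 ylab = "thrombus area (px)", ...)
  graphics::points(m$time_s[m$active], m$tsa_px[m$active], pch = 16,
                   cex = 0.5)
  if (!is.null(truth))
    graphics::lines(m$time_s, truth, col = "red", lty = 2)
  if (!is.na(x$tta_s)) graphics::abline(v = x$tta_s, col = "gray", lty = 3)
  invisible(x)
}
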