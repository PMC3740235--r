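# Evaluation metrics and sequence/label/measure I/O.
# Label legend (fixed): 0 background, 1 vessel, 2 thrombus, 3 forbidden.
# For evaluation, forbidden pixels count as background.

.eval_labels <- function(l) {
  l <- as.integer(l)
  l[l == 3L] <- 0L
  l
}

#' Rand index between two partitions
#'
#' Fraction of pixel pairs on which the two partitions agree (both pairs
#' joint, or both pairs split), computed with the contingency-table
#' identity.  Forbidden-class pixels are scored as background.
#'
#' @param labels_a,labels_b label maps of equal shape.
#' @return scalar in `[0, 1]`; 1 for identical partitions.
#' @export
rand_index <- function(labels_a, labels_b) {
  if (!identical(dim(labels_a), dim(labels_b)) ||
      length(labels_a) != length(labels_b))
    stop_dts("shape_mismatch", "label maps differ in shape")
  a <- .eval_labels(labels_a); b <- .eval_labels(labels_b)
  N <- length(a)
  ct <- table(a, b)
  sij <- sum(choose(ct, 2))
  sa <- sum(choose(rowSums(ct), 2))
  sb <- sum(choose(colSums(ct), 2))
  (choose(N, 2) - sa - sb + 2 * sij) / choose(N, 2)
}

#' Dice coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty (a
#' correctly absent region, e.g. pre-attachment thrombus) and 0 when only
#' one is.
#'
#' @param mask_a,mask_b binary masks of equal shape.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop_dts("shape_mismatch", "masks differ in shape")
  a <- mask_a != 0; b <- mask_b != 0
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

#' Cross-stability of a set of masks
#'
#' Mean of all pairwise Dice coefficients, diagonal included:
#' \eqn{\Sigma = n^{-2} \sum_p \sum_q DC(m_p, m_q)}.  Measures the
#' robustness of repeated segmentations to initialization; 1 when all
#' masks coincide.
#'
#' @param masks list of binary masks of equal shape.
#' @return scalar in `(0, 1]`.
#' @export
cross_stability <- function(masks) {
  n <- length(masks)
  stopifnot(n >= 1L)
  tot <- n  # diagonal terms are 1
  if (n > 1) {
    for (p in seq_len(n - 1)) for (q in (p + 1):n)
      tot <- tot + 2 * dice(masks[[p]], masks[[q]])
  }
  tot / n^2
}

# ---- sequence I/O -------------------------------------------------------

#' Read a grayscale image sequence
#'
#' Accepts a multi-page TIFF file or a directory of numbered PNG/TIFF
#' frames (lexicographic order).  8- and 16-bit images are supported and
#' normalized to `[0, 1]`; mixing bit depths across frames is an error.
#' Multi-channel frames are reduced to their first channel.
#'
#' @param path file or directory.
#' @return numeric array `H x W x T`.
#' @export
read_sequence <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L)
      stop_dts("empty_directory", "no PNG/TIFF frames in %s", path)
    frames <- list(); bits <- integer(length(files))
    for (i in seq_along(files)) {
      f <- files[i]
      fr <- tryCatch({
        if (grepl("\\.png$", f, ignore.case = TRUE)) {
          img <- png::readPNG(f, info = TRUE)
          bits[i] <- attr(img, "info")$bit.depth %||% 8L
          img
        } else {
          img <- tiff::readTIFF(f, info = TRUE)
          bits[i] <- attr(img, "bits.per.sample") %||% 8L
          img
        }
      }, error = function(e)
        stop_dts("unreadable_file", "cannot read frame %s: %s", f,
                 conditionMessage(e)))
      frames[[i]] <- .first_channel(fr)
    }
    if (length(unique(bits[bits > 0])) > 1L)
      stop_dts("mixed_bit_depth", "frames mix bit depths: %s",
               paste(unique(bits), collapse = ", "))
    return(.stack_frames(frames, path))
  }
  if (!file.exists(path))
    stop_dts("unreadable_file", "no such file: %s", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e)
                      stop_dts("unreadable_file", "cannot read %s: %s", path,
                               conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  bits <- vapply(pages, function(p) attr(p, "bits.per.sample") %||% 8L,
                 numeric(1))
  if (length(unique(bits)) > 1L)
    stop_dts("mixed_bit_depth", "pages mix bit depths: %s",
             paste(unique(bits), collapse = ", "))
  .stack_frames(lapply(pages, .first_channel), path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.first_channel <- function(img) {
  if (length(dim(img)) == 3L) img[, , 1] else img
}

.stack_frames <- function(frames, path) {
  dms <- unique(lapply(frames, dim))
  if (length(dms) > 1L)
    stop_dts("unreadable_file", "frames in %s differ in size", path)
  array(unlist(frames), c(dms[[1]], length(frames)))
}

#' Write an image sequence as a multi-page TIFF
#'
#' @param path output file.
#' @param sequence `H x W x T` array in `[0, 1]`.
#' @param bits 8 or 16 bits per sample.
#' @export
write_sequence <- function(path, sequence, bits = 16L) {
  frames <- lapply(seq_len(dim(sequence)[3]),
                   function(t) pmin(pmax(sequence[, , t], 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = bits)
  invisible(path)
}

#' Write label maps as an 8-bit multi-page TIFF
#'
#' Labels use the fixed legend (0 background, 1 vessel, 2 thrombus,
#' 3 forbidden) stored as raw 8-bit values.
#'
#' @param path output file.
#' @param labels a label matrix or list of label matrices.
#' @export
write_labels <- function(path, labels) {
  if (is.matrix(labels)) labels <- list(labels)
  frames <- lapply(labels, function(l) matrix(as.numeric(l) / 255,
                                              nrow(l), ncol(l)))
  tiff::writeTIFF(frames, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read label maps written by [write_labels()]
#'
#' @param path label TIFF file.
#' @return list of integer label matrices.
#' @export
read_labels <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    m <- round(.first_channel(p) * 255)
    storage.mode(m) <- "integer"
    m
  })
}

#' Write track measures as CSV plus a JSON sidecar
#'
#' The CSV has columns frame, time_s, tsa_px, tsa_um2, vessel_px,
#' active_flag; the sidecar carries the TTA, metadata and a configuration
#' echo.
#'
#' @param path_prefix output path without extension; writes
#'   `<prefix>.csv` and `<prefix>.json`.
#' @param result a `dts_track`.
#' @export
write_measures <- function(path_prefix, result) {
  stopifnot(inherits(result, "dts_track"))
  m <- result$measures
  names(m)[names(m) == "active"] <- "active_flag"
  utils::write.csv(m, paste0(path_prefix, ".csv"), row.names = FALSE)
  side <- list(tta_s = if (is.na(result$tta_s)) NULL else result$tta_s,
               active_frames = result$active_frames,
               meta = result$meta[c("frame_rate", "pixel_size", "decimation",
                                    "min_area")],
               config = unclass(result$meta$config))
  jsonlite::write_json(side, paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path_prefix)
}

# ---- configuration files ------------------------------------------------

#' Read or write a solver configuration (YAML)
#'
#' @param file YAML file path.
#' @return [read_config()]: a `dts_config`; unknown keys are rejected.
#' @export
read_config <- function(file) {
  vals <- yaml::read_yaml(file)
  if (is.null(vals)) vals <- list()
  # YAML 1.1 parses a bare key `n` as the boolean FALSE; map it back to
  # the model-order field
  names(vals)[names(vals) == "FALSE"] <- "n"
  known <- names(formals(solver_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop_dts("degenerate_input", "unknown config keys: %s",
             paste(bad, collapse = ", "))
  do.call(solver_config, vals)
}

#' @rdname read_config
#' @param config a `dts_config`.
#' @export
write_config <- function(file, config) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}
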