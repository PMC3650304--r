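# Binary preprocessing of grayscale stacks: background subtraction (free
# mode) or linear histogram remap (restrained mode), thresholding, and
# morphological clean-up (small/border object rejection, hole filling),
# leaving the larva as the single foreground component.

label_components <- function(mask) {
  EBImage::bwlabel(EBImage::Image(mask * 1))
}

component_areas <- function(lab) {
  v <- as.numeric(lab)
  v <- v[v > 0]
  if (!length(v)) return(integer(0))
  tabulate(v)
}

touches_border <- function(lab) {
  n <- max(lab)
  if (n == 0) return(integer(0))
  edge <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  edge[edge > 0]
}

clean_mask <- function(mask, min_area, max_area = Inf, fill_holes = TRUE,
                       drop_border = TRUE) {
  lab <- label_components(mask)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
  if (max(lab) == 0) return(mask & FALSE)
  areas <- component_areas(lab)
  keep <- which(areas >= min_area & areas <= max_area)
  if (drop_border) keep <- setdiff(keep, touches_border(lab))
  out <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  if (fill_holes && any(out)) {
    filled <- EBImage::fillHull(EBImage::Image(out * 1))
    out <- matrix(as.numeric(EBImage::imageData(filled)) > 0.5,
                  nrow(mask), ncol(mask))
  }
  out
}

#' Preprocess a free-swimming stack into binary larva masks
#'
#' Subtracts a background image, thresholds the difference image
#' (automatic Otsu threshold by default), rejects components below
#' `min_area` or touching the image border, and fills holes. After
#' cleaning, each valid frame contains the larva as its only foreground
#' component.
#'
#' @param stack numeric array `[y, x, frame]`, gray levels 0-255.
#' @param background background frame (same shape as one frame).
#' @param threshold binarization threshold on the 0-1 scaled difference
#'   image, or `NULL` for Otsu.
#' @param min_area minimum component area, px.
#' @param fill_holes fill holes in the kept components.
#' @return list with `mask` (logical array) and `valid` (logical per
#'   frame; `FALSE` when no foreground survives cleaning).
#' @export
preprocess_free <- function(stack, background, threshold = NULL,
                            min_area = 150, fill_holes = TRUE) {
  stopifnot(all(dim(background) == dim(stack)[1:2]))
  n <- dim(stack)[3]
  mask <- array(FALSE, dim(stack))
  valid <- logical(n)
  for (i in seq_len(n)) {
    d <- pmax(stack[, , i] - background, 0) / 255
    if (max(d) <= 1e-3) next
    # threshold the background-subtracted image directly: an automatic
    # Otsu split is stable on the bimodal difference image, whereas any
    # fixed cut on the equalized scale erodes the dimmest silhouette
    # pixels (equalization stretches them down to the background plateau)
    thr <- if (is.null(threshold)) EBImage::otsu(EBImage::Image(d))
           else threshold
    m <- clean_mask(d > thr, min_area, fill_holes = fill_holes)
    mask[, , i] <- m
    valid[i] <- any(m)
  }
  list(mask = mask, valid = valid)
}

#' Preprocess a restrained-larva stack into binary masks
#'
#' No background reference is available in restrained recordings, so a
#' linear histogram remap suppresses background values and amplifies fish
#' values before a fixed threshold is applied; morphological clean-up is
#' identical to the free-mode path.
#'
#' @param stack numeric array `[y, x, frame]`, gray levels 0-255.
#' @param remap_factor linear gain (> 1) applied around the remap pivot.
#' @param fixed_threshold threshold on the remapped 0-255 scale.
#' @param pivot gray level mapped to itself; defaults to the per-frame
#'   median (background level).
#' @param min_area minimum component area, px.
#' @return list with `mask` and `valid` as in [preprocess_free()].
#' @export
preprocess_restrained <- function(stack, remap_factor = 3,
                                  fixed_threshold = 128, pivot = NULL,
                                  min_area = 150) {
  if (remap_factor <= 1) stop("remap_factor must be > 1")
  n <- dim(stack)[3]
  mask <- array(FALSE, dim(stack))
  valid <- logical(n)
  for (i in seq_len(n)) {
    f <- stack[, , i]
    pv <- if (is.null(pivot)) stats::median(f) else pivot
    remapped <- pmin(pmax((f - pv) * remap_factor, 0), 255)
    m <- clean_mask(remapped > fixed_threshold, min_area)
    mask[, , i] <- m
    valid[i] <- any(m)
  }
  list(mask = mask, valid = valid)
}

#' Isolate small moving objects (the prey) in a stack
#'
#' Same morphology as the larva path but with a large-object rejection
#' step, leaving the paramecium-sized particle as the only candidate
#' component per frame.
#'
#' @inheritParams preprocess_free
#' @param max_area maximum component area, px; larger objects (the fish)
#'   are rejected.
#' @param min_area minimum component area, px.
#' @return list with `mask` and `valid` as in [preprocess_free()].
#' @export
preprocess_prey <- function(stack, background, threshold = NULL,
                            min_area = 3, max_area = 120) {
  stopifnot(all(dim(background) == dim(stack)[1:2]))
  n <- dim(stack)[3]
  mask <- array(FALSE, dim(stack))
  valid <- logical(n)
  for (i in seq_len(n)) {
    d <- pmax(stack[, , i] - background, 0) / 255
    if (max(d) <= 1e-3) next
    thr <- if (is.null(threshold)) EBImage::otsu(EBImage::Image(d))
           else threshold
    m <- clean_mask(d > thr, min_area, max_area = max_area,
                    drop_border = FALSE)
    mask[, , i] <- m
    valid[i] <- any(m)
  }
  list(mask = mask, valid = valid)
}
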