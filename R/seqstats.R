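# Sequence-level statistics: inter-bout intervals, reflected straight-line
# fits, folded 10-degree angle histograms, and the two-step eye-convergence
# criterion that marks the start of a prey-capture sequence.

#' Inter-bout intervals of a time-ordered bout table
#'
#' `IBI_j = onset_{j+1} - offset_j`.
#'
#' @param bouts data.frame with `onset_ms` and `offset_ms`, time-ordered.
#' @return numeric vector of IBIs, ms (length `nrow(bouts) - 1`).
#' @export
compute_ibis <- function(bouts) {
  n <- nrow(bouts)
  if (n < 2) return(numeric(0))
  if (any(diff(bouts$onset_ms) <= 0) ||
      any(bouts$onset_ms[-1] < bouts$offset_ms[-n]))
    stop("bouts overlap or are out of order")
  bouts$onset_ms[-1] - bouts$offset_ms[-n]
}

#' Straight-line fit with the plotting reflection conventions
#'
#' `reflect_mode = "point"` point-reflects pairs with `x < 0` about the
#' origin (negates both coordinates; prey-on-left data folded onto the
#' right); `"mirror_x"` negates only `x` for pairs with `x < 0`
#' (leftward turns mirrored about the y-axis); `"none"` fits as is. The
#' least-squares slope/intercept and Pearson r are computed on the
#' reflected data.
#'
#' @param xs,ys numeric vectors (degrees).
#' @param reflect_mode one of `"none"`, `"point"`, `"mirror_x"`.
#' @return a `fit_result` list: `slope`, `intercept`, `r`, `n`,
#'   `reflect_mode`.
#' @export
linefit <- function(xs, ys, reflect_mode = c("none", "point", "mirror_x")) {
  reflect_mode <- match.arg(reflect_mode)
  keep <- is.finite(xs) & is.finite(ys)
  xs <- xs[keep]; ys <- ys[keep]
  if (length(xs) < 3) stop("need at least 3 points")
  if (reflect_mode == "point") {
    neg <- xs < 0
    xs[neg] <- -xs[neg]; ys[neg] <- -ys[neg]
  } else if (reflect_mode == "mirror_x") {
    neg <- xs < 0
    xs[neg] <- -xs[neg]
  }
  if (stats::sd(xs) == 0) stop("zero x-variance")
  fit <- stats::lm(ys ~ xs)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = stats::cor(xs, ys), n = length(xs),
                 reflect_mode = reflect_mode),
            class = "fit_result")
}

#' Folded 10-degree bin index for angles
#'
#' Bin 1 holds |a| < 5 degrees; bin m >= 2 holds |a| in
#' [10 m - 15, 10 m - 5).
#' @param a angles, degrees.
#' @export
folded_bin <- function(a) as.integer(floor((abs(a) + 5) / 10) + 1)

#' Folded angle histograms and the normalized turn histogram
#'
#' Groups `phi_pre` and `dtheta` into folded-absolute 10-degree bins and
#' normalizes the turn-angle counts by the target-angle counts per bin.
#'
#' @param phi_pre fish-target angles before the swim, degrees.
#' @param dtheta changes in orientation, degrees.
#' @return data.frame: `bin`, `center_deg`, `phi_count`, `dtheta_count`,
#'   `normalized` (NA where the target-angle count is 0).
#' @export
angle_histograms <- function(phi_pre, dtheta) {
  bp <- folded_bin(phi_pre)
  bd <- folded_bin(dtheta)
  nb <- max(c(bp, bd, 1))
  phi_count <- tabulate(bp, nb)
  dtheta_count <- tabulate(bd, nb)
  normalized <- ifelse(phi_count > 0, dtheta_count / phi_count, NA_real_)
  data.frame(bin = seq_len(nb), center_deg = (seq_len(nb) - 1) * 10,
             phi_count = phi_count, dtheta_count = dtheta_count,
             normalized = normalized)
}

#' Classify the start of a prey-capture sequence from eye angles
#'
#' Implements the two-step convergence criterion: the sequence starts at
#' the first bout after which the contralateral eye has crossed
#' `contra_high` (near-maximal convergence) and the ipsilateral eye
#' crosses `ipsi_high` by the following bout boundary.
#'
#' @param eye_course data.frame with `contra` and `ipsi` angles (degrees,
#'   nasal-positive) at each bout boundary (row 1 = before the first
#'   bout, row j+1 = after bout j).
#' @param contra_high,ipsi_high thresholds, degrees; defaults midway
#'   between the measured pre/post convergence levels.
#' @return the starting bout index, or `NA` with attribute `reason`.
#' @export
classify_sequence_start <- function(eye_course, contra_high = 21.9,
                                    ipsi_high = 24.0) {
  if (is.null(eye_course) || !nrow(eye_course) ||
      any(!is.finite(eye_course$contra)) || any(!is.finite(eye_course$ipsi)))
    return(structure(NA_integer_, reason = "missing eye data"))
  nb <- nrow(eye_course) - 1
  for (j in seq_len(nb)) {
    contra_ok <- eye_course$contra[j + 1] >= contra_high
    ipsi_ok <- if (j + 2 <= nb + 1)
      eye_course$ipsi[j + 2] >= ipsi_high
    else eye_course$ipsi[j + 1] >= ipsi_high
    if (contra_ok && ipsi_ok) return(j)
  }
  structure(NA_integer_, reason = "no two-step convergence")
}
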