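# Landmark-based registration accuracy metrics: per-landmark target
# registration error (TRE), its per-pair median, and the median/mean of
# per-pair medians over a set of registration pairs (MM-TRE / AM-TRE).
# With images at 1 um/px all errors are in micrometers.

#' Per-landmark target registration error
#'
#' Euclidean distance between each warped landmark and its paired fixed
#' landmark.
#'
#' @param warped,fixed paired [pointset2d()]s (pairing by row index).
#' @return Numeric vector of distances.
#' @export
tre <- function(warped, fixed) {
  if (nrow(warped) != nrow(fixed))
    hf_stop("pairing_error", "landmark sets differ in size (%d vs %d)",
            nrow(warped), nrow(fixed))
  if (nrow(warped) == 0)
    hf_stop("undefined_metric_error", "TRE of an empty landmark set is undefined")
  sqrt((warped$x - fixed$x)^2 + (warped$y - fixed$y)^2)
}

#' Median TRE of one registration pair
#' @inheritParams tre
#' @return Scalar median distance (even counts: midpoint of the two central
#'   order statistics).
#' @export
median_tre <- function(warped, fixed) median(tre(warped, fixed))

#' Median of per-pair median TREs over a set of registration pairs
#' @param pair_medians numeric vector of per-pair median TREs.
#' @return Scalar.
#' @export
mm_tre <- function(pair_medians) {
  if (length(pair_medians) == 0)
    hf_stop("undefined_metric_error", "MM-TRE over an empty pair set is undefined")
  median(pair_medians)
}

#' Mean of per-pair median TREs over a set of registration pairs
#' @inheritParams mm_tre
#' @return Scalar.
#' @export
am_tre <- function(pair_medians) {
  if (length(pair_medians) == 0)
    hf_stop("undefined_metric_error", "AM-TRE over an empty pair set is undefined")
  mean(pair_medians)
}

#' Full TRE report over one or more registration pairs
#'
#' @param pairs list of `list(warped =, fixed =)` pointset pairs.
#' @return Object of class `tre_report`: per-pair TRE vectors and medians,
#'   plus MM-TRE and AM-TRE over the same pair set.
#' @export
tre_report <- function(pairs) {
  per <- lapply(pairs, function(p) tre(p$warped, p$fixed))
  med <- vapply(per, median, 0)
  structure(list(tre = per, median_tre = med,
                 mm_tre = mm_tre(med), am_tre = am_tre(med)),
            class = "tre_report")
}

#' @export
print.tre_report <- function(x, ...) {
  cat(sprintf("<tre_report: %d pair(s), MM-TRE %.3f, AM-TRE %.3f>\n",
              length(x$tre), x$mm_tre, x$am_tre))
  invisible(x)
}
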