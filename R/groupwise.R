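# Groupwise registration of an ordered series of serial sections: chained
# neighbor affines to the fixed section, then direct nonrigid refinement of
# every moving section against the fixed section.

#' Ordered series of stained sections
#'
#' @param images list of [raster2d()]s in sectioning order.
#' @param masks optional list of [binary_mask()]s (NULL entries allowed).
#' @param fixed_index index of the fixed (reference) section; defaults to
#'   the last section of the series.
#' @param skip indices of damaged sections to bridge over in the affine
#'   chain (they receive no transform).
#' @return An object of class `section_series`.
#' @export
section_series <- function(images, masks = NULL, fixed_index = length(images),
                           skip = integer(0)) {
  if (length(images) < 2) hf_stop("type_error", "a series needs >= 2 sections")
  if (fixed_index < 1 || fixed_index > length(images))
    hf_stop("type_error", "fixed_index %d out of range", fixed_index)
  if (fixed_index %in% skip) hf_stop("type_error", "fixed section cannot be skipped")
  if (is.null(masks)) masks <- vector("list", length(images))
  structure(list(images = images, masks = masks,
                 fixed_index = as.integer(fixed_index),
                 skip = as.integer(skip)),
            class = "section_series")
}

series_masks <- function(series, opts) {
  lapply(seq_along(series$images), function(i) {
    if (!is.null(series$masks[[i]])) series$masks[[i]]
    else segment_tissue(series$images[[i]], opts$min_region_um2)
  })
}

#' Chained neighbor affine registration of a section series
#'
#' A pairwise affine registration is computed between each pair of
#' neighboring (non-skipped) sections; each moving section's transform to
#' the fixed space is the composition of the neighbor affines along the
#' series (inverted composition when the section lies beyond the fixed
#' index).  All returned affines act between ORIGINAL image spaces.
#'
#' @param series a [section_series()].
#' @param opts a [reg_options()] list.
#' @return Named list of [affine_transform()]s, one per moving section
#'   (`NULL` for skipped sections and the identity-free fixed section).
#' @export
serial_affine_chain <- function(series, opts = reg_options()) {
  masks <- series_masks(series, opts)
  active <- setdiff(seq_along(series$images), series$skip)
  fi <- series$fixed_index
  # neighbor affines between consecutive ACTIVE sections, in series order
  neigh <- list()
  for (k in seq_len(length(active) - 1)) {
    i <- active[k]; j <- active[k + 1]
    res <- tryCatch(
      register_pair(series$images[[i]], series$images[[j]], masks[[i]],
                    masks[[j]], opts, nonrigid = FALSE),
      error = function(e)
        hf_stop("chain_error", "neighbor registration failed for pair (%d, %d): %s",
                i, j, conditionMessage(e)))
    neigh[[k]] <- affine_in_original_space(res)
  }
  out <- vector("list", length(series$images))
  pos_f <- match(fi, active)
  for (k in seq_along(active)) {
    i <- active[k]
    if (i == fi) { out[[i]] <- affine_identity(); next }
    if (k < pos_f) {
      a <- neigh[[k]]
      if (pos_f - 1 > k) for (m in (k + 1):(pos_f - 1)) a <- affine_compose(neigh[[m]], a)
      out[[i]] <- a
    } else {
      # beyond the fixed section: compose inverses back down the series
      a <- affine_invert(neigh[[k - 1]])
      if (k - 2 >= pos_f) for (m in seq(k - 2, pos_f)) a <- affine_compose(affine_invert(neigh[[m]]), a)
      out[[i]] <- a
    }
  }
  names(out) <- paste0("section_", seq_along(out))
  out
}

#' Groupwise registration of a section series
#'
#' Every moving section is first carried into the fixed space by the chained
#' neighbor affines ([serial_affine_chain()]), then nonrigidly registered
#' DIRECTLY against the fixed section with that chained affine as
#' initialization; the result per section is a composited
#' [transform_chain()] to the fixed space.  Sections are independent after
#' the affine chain, so the per-section work can run through any `map_fn`
#' with identical results.
#'
#' @param series a [section_series()].
#' @param opts a [reg_options()] list.
#' @param map_fn a `lapply`-compatible map (pluggable parallelism; default
#'   sequential `lapply`).
#' @return Named list of [transform_chain()]s (`NULL` for skipped sections
#'   and for the fixed section itself).
#' @export
groupwise_register <- function(series, opts = reg_options(), map_fn = lapply) {
  masks <- series_masks(series, opts)
  fi <- series$fixed_index
  chains_aff <- serial_affine_chain(series, opts)
  movers <- setdiff(seq_along(series$images), c(series$skip, fi))
  res <- map_fn(movers, function(i) {
    tryCatch(
      register_pair(series$images[[i]], series$images[[fi]], masks[[i]],
                    masks[[fi]], opts, nonrigid = TRUE,
                    init_affine = chains_aff[[i]])$chain,
      error = function(e)
        hf_stop("chain_error", "groupwise registration failed for section %d: %s",
                i, conditionMessage(e)))
  })
  out <- vector("list", length(series$images))
  out[movers] <- res
  names(out) <- paste0("section_", seq_along(out))
  out
}
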