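# Pairwise registration driver: preprocessing -> affine -> nonrigid ->
# transform chain from the original moving space to the original fixed space.

#' Register a moving stained section onto a fixed stained section
#'
#' Full pairwise pipeline: tissue segmentation (unless masks are supplied),
#' affine-stage preprocessing (with mean-shift denoising), seeded rigid
#' random search plus multi-resolution affine refinement, nonrigid-stage
#' preprocessing (without denoising) and the greedy diffeomorphic nonrigid
#' stage initialized by the affine, all collected into a [transform_chain()]
#' between the ORIGINAL image spaces (preprocessing bookkeeping included).
#'
#' @param moving,fixed [raster2d()] stained images.
#' @param moving_mask,fixed_mask optional [binary_mask()]s.
#' @param opts a [reg_options()] list.
#' @param nonrigid run the nonrigid stage (default `TRUE`).
#' @param init_affine optional affine in ORIGINAL spaces (moving to fixed)
#'   replacing the affine stage (used by the groupwise mode).
#' @return An object of class `registration_result`: list with `chain`
#'   (original moving space to original fixed space), `affine` and `field`
#'   (working space), the two preprocessing bookkeeping records and the
#'   final similarity.
#' @export
register_pair <- function(moving, fixed, moving_mask = NULL, fixed_mask = NULL,
                          opts = reg_options(), nonrigid = TRUE,
                          init_affine = NULL) {
  if (is.null(moving_mask)) moving_mask <- segment_tissue(moving, opts$min_region_um2)
  if (is.null(fixed_mask)) fixed_mask <- segment_tissue(fixed, opts$min_region_um2)
  field <- NULL
  if (is.null(init_affine)) {
    pp <- prepare_pair(moving, fixed, moving_mask, fixed_mask, "affine", opts)
    aff <- affine_register(pp$moving, pp$fixed, opts)
  } else {
    # express the supplied original-space affine in the working spaces
    pp <- prepare_pair(moving, fixed, moving_mask, fixed_mask, "nonrigid", opts)
    aff <- affine_compose(pp$fixed$bookkeeping$affine,
                          affine_compose(init_affine,
                                         affine_invert(pp$moving$bookkeeping$affine)))
  }
  if (nonrigid) {
    ppn <- prepare_pair(moving, fixed, moving_mask, fixed_mask, "nonrigid", opts)
    field <- nonrigid_register(ppn$moving, ppn$fixed, aff, opts)
    bk_m <- ppn$moving$bookkeeping$affine
    bk_f <- ppn$fixed$bookkeeping$affine
  } else {
    bk_m <- pp$moving$bookkeeping$affine
    bk_f <- pp$fixed$bookkeeping$affine
  }
  steps <- list(chain_step("affine", from = "moving", to = "work_m", fwd = bk_m),
                chain_step("affine", from = "work_m", to = "work_f", fwd = aff))
  if (!is.null(field))
    steps <- c(steps, list(chain_step("field", from = "work_f", to = "work_f",
                                      field = field)))
  steps <- c(steps, list(chain_step("affine", from = "work_f", to = "fixed",
                                    fwd = affine_invert(bk_f))))
  chain <- transform_chain(steps, raster_shape(moving), raster_shape(fixed),
                           moving$resolution_um)
  structure(list(chain = chain, affine = aff, field = field,
                 moving_bookkeeping = bk_m, fixed_bookkeeping = bk_f,
                 similarity = if (!is.null(field)) attr(field, "similarity")
                              else attr(aff, "similarity")),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result: %s, similarity %.4f>\n",
              if (is.null(x$field)) "affine" else "affine + nonrigid",
              x$similarity))
  invisible(x)
}

# original-space affine (moving orig -> fixed orig) of an affine-only result
affine_in_original_space <- function(res) {
  affine_compose(affine_invert(res$fixed_bookkeeping),
                 affine_compose(res$affine, res$moving_bookkeeping))
}
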