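# Fusion of registered pixel-level source measurements into spot-level
# target organization via area-fraction-weighted statistics, plus the
# coverage / tissue-type filters and export formats.

#' Per-spot overlap weights between target and source reference matrices
#'
#' For each target spot the co-labeled raster cells are counted per source
#' data point; weights are the area fractions of the spot's covered area
#' (they sum to 1 for every spot with any overlap).
#'
#' @param target_ref,source_ref [reference_matrix()]s in the SAME (target)
#'   image space, i.e. the source matrix already warped.
#' @return An object of class `overlap_map`: named list (target id ->
#'   data.frame with `source_id`, `cells`, `weight`), with attributes
#'   `spot_cells` (total labeled cells per target id, overlap or not) and
#'   `resolution_um`.
#' @export
overlap_weights <- function(target_ref, source_ref) {
  if (!all(dim(target_ref$labels) == dim(source_ref$labels)))
    hf_stop("space_error",
            "reference matrices differ in shape; warp the source into the target space first")
  t <- target_ref$labels; s <- source_ref$labels
  both <- t > 0L & s > 0L
  spot_cells <- tabulate(t[t > 0L], nbins = length(target_ref$ids))
  names(spot_cells) <- target_ref$ids
  out <- structure(list(), spot_cells = spot_cells,
                   resolution_um = target_ref$resolution_um,
                   class = "overlap_map")
  if (!any(both)) return(out)
  tv <- t[both]; sv <- s[both]
  key <- (as.numeric(tv) - 1) * length(source_ref$ids) + as.numeric(sv)
  o <- order(key)
  r <- rle(key[o])
  tk <- as.integer((r$values - 1) %/% length(source_ref$ids)) + 1L
  sk <- as.integer((r$values - 1) %% length(source_ref$ids)) + 1L
  m <- list()
  for (ti in unique(tk)) {
    sel <- tk == ti
    cells <- r$lengths[sel]
    m[[target_ref$ids[ti]]] <- data.frame(
      source_id = source_ref$ids[sk[sel]], cells = cells,
      weight = cells / sum(cells), stringsAsFactors = FALSE)
  }
  attributes(m) <- c(attributes(m),
                     list(spot_cells = spot_cells,
                          resolution_um = target_ref$resolution_um))
  class(m) <- "overlap_map"
  m
}

#' Weighted summary statistics
#'
#' Weighted mean `sum(w * v)`, population weighted standard deviation
#' `sqrt(sum(w * (v - mean)^2))`, lower weighted median (smallest value with
#' cumulative weight >= 0.5 after sorting by value) and unweighted extremes
#' of the contributing values.
#'
#' @param values numeric vector.
#' @param weights non-negative weights summing to 1.
#' @return Named list `min`, `max`, `mean`, `std`, `median`.
#' @export
weighted_stats <- function(values, weights) {
  if (length(values) == 0)
    return(list(min = NA_real_, max = NA_real_, mean = NA_real_,
                std = NA_real_, median = NA_real_, missing = TRUE))
  if (length(values) != length(weights))
    hf_stop("type_error", "values and weights differ in length")
  if (abs(sum(weights) - 1) > 1e-6)
    hf_stop("type_error", "weights must sum to 1")
  m <- sum(weights * values)
  o <- order(values)
  cw <- cumsum(weights[o])
  med <- values[o][which(cw >= 0.5 - 1e-12)[1]]
  list(min = min(values), max = max(values), mean = m,
       std = sqrt(sum(weights * (values - m)^2)), median = med)
}

#' Fuse source measurements into target spots
#'
#' Computes the weighted statistics of every measure over each target spot's
#' overlapping source data points, using the area fractions as weights.
#' Spots without any overlap are emitted with `no_overlap = TRUE` and NA
#' statistics rather than dropped, so downstream joins stay aligned.
#'
#' @param source_table a [measurement_table()] covering all source ids that
#'   appear in `weights`.
#' @param weights an [overlap_map()] from [overlap_weights()].
#' @param all_spot_ids spot ids to emit (default: every id with labeled
#'   cells in the target reference matrix).
#' @return A data.frame of class `fused_spot_table`: one row per spot;
#'   columns `spot_id`, `<measure>.min/.max/.mean/.std/.median` per measure,
#'   `overlap_area_um2`, `n_source`, `no_overlap`.
#' @export
fuse <- function(source_table, weights, all_spot_ids = NULL) {
  if (is.null(all_spot_ids)) all_spot_ids <- names(attr(weights, "spot_cells"))
  needed <- unique(unlist(lapply(weights, function(d) d$source_id)))
  missing_ids <- setdiff(needed, source_table$ids)
  if (length(missing_ids))
    hf_stop("integrity_error", "source ids missing from measurement table: %s",
            paste(head(missing_ids, 5), collapse = ", "))
  measures <- colnames(source_table$values)
  res_um <- attr(weights, "resolution_um")
  stat_names <- c("min", "max", "mean", "std", "median")
  cols <- as.vector(outer(measures, stat_names, paste, sep = "."))
  out <- data.frame(spot_id = all_spot_ids, stringsAsFactors = FALSE)
  for (cn in cols) out[[cn]] <- NA_real_
  out$overlap_area_um2 <- 0
  out$n_source <- 0L
  out$no_overlap <- TRUE
  rownames(out) <- all_spot_ids
  for (sid in intersect(all_spot_ids, names(weights))) {
    d <- weights[[sid]]
    vi <- match(d$source_id, source_table$ids)
    for (ms in measures) {
      st <- weighted_stats(source_table$values[vi, ms], d$weight)
      out[sid, paste(ms, stat_names, sep = ".")] <-
        unlist(st[stat_names])
    }
    out[sid, "overlap_area_um2"] <- sum(d$cells) * res_um^2
    out[sid, "n_source"] <- nrow(d)
    out[sid, "no_overlap"] <- FALSE
  }
  class(out) <- c("fused_spot_table", "data.frame")
  out
}

#' Per-spot tissue coverage and the coverage filter
#'
#' Coverage is the fraction of a spot's labeled raster cells that fall
#' inside the tissue mask.  The filter keeps spots with coverage >= the
#' threshold (strict "less than" removal: a spot at exactly the threshold
#' survives).
#'
#' @param target_ref a [reference_matrix()].
#' @param tissue_mask a [binary_mask()] in the same image space.
#' @return `spot_coverage`: named numeric vector of fractions per spot id.
#' @export
spot_coverage <- function(target_ref, tissue_mask) {
  if (!all(dim(target_ref$labels) == dim(tissue_mask$pixels)))
    hf_stop("space_error", "tissue mask and reference matrix differ in shape")
  lab <- target_ref$labels
  n_all <- tabulate(lab[lab > 0L], nbins = length(target_ref$ids))
  inm <- lab[lab > 0L & tissue_mask$pixels]
  n_in <- tabulate(inm, nbins = length(target_ref$ids))
  frac <- ifelse(n_all > 0, n_in / n_all, NA_real_)
  setNames(frac, target_ref$ids)
}

#' @rdname spot_coverage
#' @param coverage named vector from [spot_coverage()].
#' @param threshold minimum coverage kept (default 0.8).
#' @return `filter_by_coverage`: character vector of surviving spot ids.
#' @export
filter_by_coverage <- function(coverage, threshold = 0.8) {
  names(coverage)[!is.na(coverage) & coverage >= threshold]
}

#' Assign a tissue-type label to each spot from an annotation raster
#'
#' Per spot, the per-label area fractions over its raster cells are
#' computed; the spot is assigned the majority label if its fraction reaches
#' `min_fraction`, otherwise left unassigned (NA).
#'
#' @param target_ref a [reference_matrix()].
#' @param annotation integer label raster (0 = unannotated) in the same
#'   image space, or a `reference_matrix`-like list with `labels`/`ids`.
#' @param annotation_names optional names for annotation labels.
#' @param min_fraction majority threshold (default 0.5).
#' @return A data.frame of class `spot_annotation`: `spot_id`, `label`
#'   (character or NA) and one `frac_<label>` column per annotation class.
#' @export
assign_tissue_type <- function(target_ref, annotation, annotation_names = NULL,
                               min_fraction = 0.5) {
  ann <- if (is.list(annotation)) annotation$labels else annotation
  if (!all(dim(target_ref$labels) == dim(ann)))
    hf_stop("space_error", "annotation raster and reference matrix differ in shape")
  K <- max(ann, 0L)
  if (K == 0L)
    return(structure(data.frame(spot_id = target_ref$ids, label = NA_character_,
                                stringsAsFactors = FALSE),
                     class = c("spot_annotation", "data.frame")))
  if (is.null(annotation_names))
    annotation_names <- if (is.list(annotation) && !is.null(annotation$ids))
      annotation$ids else as.character(seq_len(K))
  lab <- target_ref$labels
  sel <- lab > 0L
  tv <- lab[sel]; av <- ann[sel]
  n_all <- tabulate(tv, nbins = length(target_ref$ids))
  fr <- sapply(seq_len(K), function(k)
    tabulate(tv[av == k], nbins = length(target_ref$ids))) / pmax(n_all, 1)
  fr <- matrix(fr, ncol = max(K, 1))
  best <- max.col(fr, ties.method = "first")
  bestf <- fr[cbind(seq_len(nrow(fr)), best)]
  label <- ifelse(n_all > 0 & bestf >= min_fraction, annotation_names[best], NA)
  out <- data.frame(spot_id = target_ref$ids, label = label,
                    stringsAsFactors = FALSE)
  for (k in seq_len(K)) out[[paste0("frac_", annotation_names[k])]] <- fr[, k]
  class(out) <- c("spot_annotation", "data.frame")
  out
}

#' Keep spots whose tissue type matches between target and source sections
#'
#' @param target_ann,source_ann [assign_tissue_type()] results over the
#'   same spot ids.
#' @return Character vector of spot ids assigned in both and equal.
#' @export
tissue_type_match <- function(target_ann, source_ann) {
  m <- merge(target_ann[, c("spot_id", "label")],
             source_ann[, c("spot_id", "label")], by = "spot_id")
  m$spot_id[!is.na(m$label.x) & !is.na(m$label.y) & m$label.x == m$label.y]
}

#' Sham-rotate a registration chain (negative integration control)
#'
#' Appends a rotation about the fixed-image center to the chain, producing
#' the deliberately mis-registered control used to show that correct
#' integration carries signal (default 180 degrees: (x, y) maps to
#' (W-1-x, H-1-y)).
#'
#' @param chain a [transform_chain()].
#' @param degrees rotation angle (default 180).
#' @return The sham [transform_chain()].
#' @export
sham_rotate <- function(chain, degrees = 180) {
  fs <- chain$fixed_shape
  rot <- affine_rotation(degrees, center = c((fs[2] - 1) / 2, (fs[1] - 1) / 2))
  transform_chain(c(chain$steps, list(chain_step("affine", fwd = rot))),
                  chain$moving_shape, fs, chain$resolution_um)
}

#' Export a fused spot table
#'
#' `wide_table` writes a CSV keyed by spot id (one column per
#' measure-statistic, plus overlap area and source count); `image_stack`
#' writes a multi-page TIFF painting each spot's raster cells with its fused
#' mean, one page per measure (background 0).
#'
#' @param table a [fuse()] result.
#' @param path destination file.
#' @param mode `"wide_table"` or `"image_stack"`.
#' @param target_ref the target [reference_matrix()] (required for
#'   `image_stack`).
#' @return `path`, invisibly.
#' @export
export_fused <- function(table, path, mode = c("wide_table", "image_stack"),
                         target_ref = NULL) {
  mode <- match.arg(mode)
  if (anyDuplicated(table$spot_id))
    hf_stop("export_error", "duplicate spot ids in fused table")
  if (mode == "wide_table") {
    write.csv(as.data.frame(table), path, row.names = FALSE)
  } else {
    if (is.null(target_ref))
      hf_stop("export_error", "image_stack export needs the target reference matrix")
    means <- grep("\\.mean$", names(table), value = TRUE)
    pages <- lapply(means, function(cn) {
      v <- setNames(table[[cn]], table$spot_id)
      lut <- c(0, ifelse(is.na(v[target_ref$ids]), 0, v[target_ref$ids]))
      pg <- matrix(lut[target_ref$labels + 1L], nrow(target_ref$labels))
      mx <- max(pg, 1e-12)
      pg / mx
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Re-import a fused wide-table CSV
#' @param path CSV written by [export_fused()].
#' @return The `fused_spot_table` data.frame.
#' @export
read_fused <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("fused_spot_table", "data.frame")
  out
}
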