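#' Collapse selected markers into regions by a marker-count window
#'
#' Single-linkage chaining over the QC-surviving panel: two selected markers
#' belong to the same region when they sit on the same chromosome and their
#' panel-index gap is at most `window`; the chaining is transitive, so runs
#' of nearby markers merge into one region.  Regions are reported in genome
#' order.
#'
#' @param top Data frame from [select_top_effects()] (needs columns
#'   `marker` and `beta_mean`), or a character vector of marker names.
#' @param map Marker map of the full panel the selection was drawn from
#'   (columns `marker`, `chrom`, `pos`); panel order defines marker indices.
#' @param window Maximum panel-index gap (marker count) joining two selected
#'   markers, default 20.
#' @return Data frame of class `region_table`: `region`, `chrom`,
#'   `start_index`, `end_index`, `start_bp`, `end_bp`, `n_markers`,
#'   `top_marker`, `top_effect`, `members` (comma-separated marker names).
#' @export
group_regions <- function(top, map, window = 20) {
  stopifnot(window >= 0)
  if (is.character(top)) top <- data.frame(marker = top, beta_mean = NA_real_)
  idx <- match(top$marker, map$marker)
  if (anyNA(idx)) stop("selected markers absent from the marker map")
  o <- order(idx)
  idx <- idx[o]
  eff <- top$beta_mean[o]
  chrom <- map$chrom[idx]
  new_region <- c(TRUE, diff(idx) > window | chrom[-1] != chrom[-length(chrom)])
  rid <- cumsum(new_region)
  regions <- lapply(split(seq_along(idx), rid), function(k) {
    i <- idx[k]
    e <- eff[k]
    best <- if (all(is.na(e))) k[1] else k[which.max(abs(e))]
    data.frame(chrom = chrom[k[1]],
               start_index = min(i), end_index = max(i),
               start_bp = map$pos[min(i)], end_bp = map$pos[max(i)],
               n_markers = length(k),
               top_marker = map$marker[idx[best]],
               top_effect = eff[best],
               members = paste(map$marker[i], collapse = ","))
  })
  out <- do.call(rbind, regions)
  out <- out[order(out$chrom, out$start_bp), , drop = FALSE]
  out <- cbind(region = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("region_table", class(out))
  out
}

#' Genomic-variance share of each region
#'
#' The share of a region is the variance across animals of the DGV computed
#' from the region's member markers, divided by the variance of the DGV
#' computed from all markers.
#'
#' @param regions A `region_table` from [group_regions()].
#' @param genotypes A [genotype_matrix()] (QC-filtered panel the effects
#'   were estimated on).
#' @param effects Named per-marker posterior mean effects (e.g.
#'   `fit$beta_mean`).
#' @return `regions` with a `variance_share` column appended.
#' @export
region_variance_share <- function(regions, genotypes, effects) {
  dgv_all <- compute_dgv(genotypes, effects)
  v_all <- stats::var(dgv_all)
  if (!is.finite(v_all) || v_all <= 0)
    stop("all-marker DGV variance is zero; variance shares are undefined")
  regions$variance_share <- vapply(seq_len(nrow(regions)), function(i) {
    members <- strsplit(regions$members[i], ",", fixed = TRUE)[[1]]
    stats::var(compute_dgv(genotypes, effects, subset = members)) / v_all
  }, numeric(1))
  regions
}

#' Read literature QTL intervals from a TSV file
#'
#' The expected format is BED-like but 1-based with inclusive ends: columns
#' `chrom`, `start_bp`, `end_bp`, `trait_class`, `source`.  A curated
#' fixture of intervals for milking speed (MSPD), udder morphometrics (UT),
#' somatic-cell and mastitis traits (SCS/SCC/CM) and milk yield (MY) on the
#' Btau 4.0 assembly ships with the package:
#' `system.file("extdata", "qtl_intervals_btau4.tsv", package = "flowgwas")`.
#'
#' @param path TSV file path.
#' @return Data frame of QTL intervals.
#' @export
read_qtl_intervals <- function(path) {
  qtl <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start_bp", "end_bp", "trait_class")
  if (!all(need %in% names(qtl)))
    stop("QTL interval file must have columns ", paste(need, collapse = ", "))
  if (any(qtl$start_bp > qtl$end_bp))
    stop("malformed QTL interval: start_bp > end_bp")
  qtl
}

#' Annotate regions against QTL intervals
#'
#' A region is tagged with every trait class whose interval overlaps the
#' region's base-pair span on the same chromosome; intervals are closed, so
#' touching endpoints count as overlap.  Regions overlapping no interval are
#' tagged `"novel"`.
#'
#' @param regions A `region_table` (needs `chrom`, `start_bp`, `end_bp`).
#' @param qtl QTL interval table from [read_qtl_intervals()].
#' @return `regions` with columns `qtl_classes` (comma-separated unique
#'   trait classes, or `"novel"`) and `novel` appended.
#' @export
annotate_regions <- function(regions, qtl) {
  if (nrow(qtl) > 0 && any(qtl$start_bp > qtl$end_bp))
    stop("malformed QTL interval: start_bp > end_bp")
  tags <- vapply(seq_len(nrow(regions)), function(i) {
    if (nrow(qtl) == 0) return("novel")
    hit <- qtl$chrom == regions$chrom[i] &
      qtl$start_bp <= regions$end_bp[i] &
      qtl$end_bp >= regions$start_bp[i]
    if (!any(hit)) "novel"
    else paste(sort(unique(qtl$trait_class[hit])), collapse = ",")
  }, character(1))
  regions$qtl_classes <- tags
  regions$novel <- tags == "novel"
  regions
}
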