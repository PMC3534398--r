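#' Split sires into discovery and prediction sets by EBV reliability
#'
#' Reliability strictly greater than the threshold sends an animal to the
#' discovery set; all others go to the prediction set (so a reliability
#' exactly at the threshold predicts, it does not discover).
#'
#' @param records Data frame with columns `id` and `reliability`.
#' @param threshold Reliability cut, default 0.60.
#' @return List of class `split_spec`: `discovery` and `prediction` id
#'   vectors plus the threshold.
#' @export
split_by_reliability <- function(records, threshold = 0.60) {
  stopifnot(all(c("id", "reliability") %in% names(records)))
  disc <- records$id[records$reliability > threshold]
  pred <- records$id[records$reliability <= threshold]
  if (length(disc) == 0)
    stop("discovery set is empty at reliability threshold ", threshold)
  if (length(pred) == 0)
    warning("prediction set is empty at reliability threshold ", threshold)
  structure(list(discovery = disc, prediction = pred, threshold = threshold),
            class = "split_spec")
}

#' Direct genomic values from a marker subset
#'
#' `DGV_i = sum_{j in subset} x_ij * beta_j` on the -1/0/1 (post-imputation)
#' coding.
#'
#' @param genotypes A [genotype_matrix()] or plain matrix.
#' @param effects Named per-marker effects covering the panel.
#' @param subset Marker names (or panel indices) to sum over; `NULL` means
#'   all markers.
#' @return Numeric vector of DGVs, named by animal id where available.
#' @export
compute_dgv <- function(genotypes, effects, subset = NULL) {
  X <- if (inherits(genotypes, "genotype_matrix")) genotypes$genotypes
       else as.matrix(genotypes)
  ids <- if (inherits(genotypes, "genotype_matrix")) genotypes$ids
         else rownames(X)
  if (ncol(X) != length(effects))
    stop("effects must cover every marker in the panel")
  if (!is.null(subset)) {
    j <- if (is.character(subset)) match(subset, colnames(X)) else subset
    if (anyNA(j)) stop("subset contains markers not present in the panel")
    keep <- logical(ncol(X))
    keep[j] <- TRUE
    effects <- ifelse(keep, effects, 0)
  }
  # subset DGVs decompose additively (exactly, up to IEEE summation
  # round-off) because non-members contribute exact zeros
  dgv <- as.vector(X %*% effects)
  names(dgv) <- ids
  dgv
}

#' DGV table over nested top-effect marker subsets
#'
#' Builds per-animal DGVs for nested subsets of the markers with largest
#' absolute effects (default ladder 25, 50, 100, 300, 3000, 10000, capped at
#' the panel size) plus the full panel, and optionally for a set of
#' significant markers and its genic sub-set.
#'
#' @param genotypes A [genotype_matrix()].
#' @param effects Named per-marker posterior mean effects.
#' @param subsets Subset sizes for the |effect|-ranked ladder.
#' @param significant Optional character vector of significant marker names
#'   (adds a `"significant"` column).
#' @param genic Optional logical vector (panel order) or character vector of
#'   genic markers; with `significant`, adds a `"genic_significant"` column.
#' @return Matrix of class `dgv_table`, animals x subsets, with an `"all"`
#'   column, ordered subset columns, and the subset definition stored in
#'   attributes.
#' @export
dgv_table <- function(genotypes, effects,
                      subsets = c(25, 50, 100, 300, 3000, 10000),
                      significant = NULL, genic = NULL) {
  p <- length(effects)
  subsets <- sort(unique(pmin(subsets, p)))
  ranked <- select_top_effects(effects, k = p)$marker
  cols <- list()
  for (k in subsets) cols[[as.character(k)]] <- ranked[seq_len(k)]
  if (!is.null(significant)) {
    cols[["significant"]] <- significant
    if (!is.null(genic)) {
      genic_names <- if (is.logical(genic)) names(effects)[genic] else genic
      cols[["genic_significant"]] <- intersect(significant, genic_names)
    }
  }
  cols[["all"]] <- names(effects)
  out <- vapply(cols, function(m) compute_dgv(genotypes, effects, subset = m),
                numeric(nrow(genotypes$genotypes)))
  rownames(out) <- genotypes$ids
  attr(out, "subset_markers") <- cols
  class(out) <- c("dgv_table", class(out))
  out
}

#' Correlation between EBV and subset DGVs, and the recovery curve
#'
#' Pearson correlation between the EBVs and the DGVs of each marker subset,
#' evaluated on the animals supplied (intended to be the prediction set),
#' plus the proportion of the full-panel correlation recovered by each
#' subset.
#'
#' @param ebv Named numeric vector of EBVs (names = animal ids), or a data
#'   frame with `id` and `ebv` columns.
#' @param dgvs A [dgv_table()] (its rows are matched to the EBV ids).
#' @param ids Optional animal ids to evaluate on (e.g.
#'   `split$prediction`); default: all animals shared by `ebv` and `dgvs`.
#' @return Data frame with columns `subset`, `correlation`, `recovery`.
#' @export
correlation_recovery <- function(ebv, dgvs, ids = NULL) {
  if (is.data.frame(ebv)) {
    v <- ebv$ebv
    names(v) <- ebv$id
    ebv <- v
  }
  ids <- as.character(ids %||% intersect(names(ebv), rownames(dgvs)))
  if (length(ids) < 3) stop("at least 3 animals are required for correlations")
  e <- ebv[ids]
  d <- dgvs[ids, , drop = FALSE]
  corr <- apply(d, 2, function(col)
    if (stats::sd(col) == 0) NA_real_ else stats::cor(e, col))
  data.frame(subset = colnames(d), correlation = as.numeric(corr),
             recovery = as.numeric(corr) / corr[["all"]],
             row.names = NULL)
}

#' Proportion of genomic variance captured by each marker subset
#'
#' The overall genomic variance is the variance of the all-marker DGVs
#' across animals; each subset's proportion is the variance of its DGVs
#' divided by that total.  The `"all"` subset is exactly 1.
#'
#' @param dgvs A [dgv_table()].
#' @param ids Optional animal ids to compute variances over.
#' @return Data frame with columns `subset`, `variance`, `proportion`.
#' @export
genomic_variance_proportions <- function(dgvs, ids = NULL) {
  d <- if (is.null(ids)) dgvs else dgvs[as.character(ids), , drop = FALSE]
  if (nrow(d) < 2) stop("at least 2 animals are required")
  v <- apply(d, 2, stats::var)
  if (v[["all"]] <= 0) stop("total DGV variance is zero")
  data.frame(subset = colnames(d), variance = as.numeric(v),
             proportion = as.numeric(v) / v[["all"]], row.names = NULL)
}

#' Flag markers inside genes or their regulatory flanks
#'
#' A marker is flagged when its position falls within
#' `[gene_start - flank, gene_end + flank]` of any gene on its chromosome
#' (default flank 500 kb, treating the flanks as regulatory regions).
#'
#' @param map Marker map (`marker`, `chrom`, `pos`).
#' @param genes A `GRanges` of gene features, a data frame with `chrom`,
#'   `start`, `end`, or a GFF3 file path (gene rows are used).
#' @param flank Flank size in base pairs, default 500000.
#' @return Named logical vector, one element per marker.
#' @export
flag_gene_region_markers <- function(map, genes, flank = 5e5) {
  if (is.character(genes) && length(genes) == 1) {
    gr <- rtracklayer::import(genes)
    if ("type" %in% names(S4Vectors::mcols(gr)) && any(gr$type == "gene"))
      gr <- gr[gr$type == "gene"]
    genes <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr),
                        end = GenomicRanges::end(gr))
  } else if (methods::is(genes, "GRanges")) {
    genes <- data.frame(chrom = as.character(GenomicRanges::seqnames(genes)),
                        start = GenomicRanges::start(genes),
                        end = GenomicRanges::end(genes))
  }
  flags <- logical(nrow(map))
  names(flags) <- map$marker
  if (nrow(genes) == 0) return(flags)
  if (!any(as.character(genes$chrom) %in% as.character(map$chrom))) {
    warning("no gene chromosome names match the marker map; zero markers flagged")
    return(flags)
  }
  m_gr <- GenomicRanges::GRanges(as.character(map$chrom),
                                 IRanges::IRanges(map$pos, map$pos))
  g_gr <- GenomicRanges::GRanges(as.character(genes$chrom),
                                 IRanges::IRanges(pmax(genes$start - flank, 1),
                                                  genes$end + flank))
  hits <- GenomicRanges::findOverlaps(m_gr, g_gr)
  flags[unique(S4Vectors::queryHits(hits))] <- TRUE
  flags
}

#' Median proportion of significant-marker DGV explained by genic markers
#'
#' For each animal the ratio `DGV_gene / DGV_sig` is computed where
#' `|DGV_sig|` exceeds a small floor (10^-8 of the DGV standard deviation by
#' default, guarding against division by near-zero breeding values); the
#' median of these per-animal ratios is returned.  A variance-ratio
#' alternative (`var(DGV_gene) / var(DGV_sig)`) is available.
#'
#' @param dgv_gene DGVs from significant genic markers (named by animal).
#' @param dgv_sig DGVs from all significant markers, same animals.
#' @param method `"per_animal_median"` (default) or `"variance_ratio"`.
#' @param floor_frac Floor on `|DGV_sig|` as a fraction of `sd(DGV_sig)`.
#' @return List with `proportion`, `method`, `n_used`, and (for the median
#'   method) the per-animal `ratios`.
#' @export
gene_dgv_proportion <- function(dgv_gene, dgv_sig,
                                method = c("per_animal_median", "variance_ratio"),
                                floor_frac = 1e-8) {
  method <- match.arg(method)
  stopifnot(length(dgv_gene) == length(dgv_sig))
  if (method == "variance_ratio") {
    vs <- stats::var(dgv_sig)
    if (vs <= 0) stop("significant-marker DGV variance is zero")
    return(list(proportion = stats::var(dgv_gene) / vs,
                method = method, n_used = length(dgv_sig)))
  }
  floor <- floor_frac * stats::sd(dgv_sig)
  use <- abs(dgv_sig) > floor
  if (!any(use)) stop("all animals fall below the |DGV_sig| floor; proportion undefined")
  ratios <- dgv_gene[use] / dgv_sig[use]
  list(proportion = stats::median(ratios), method = method,
       n_used = sum(use), ratios = ratios)
}
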