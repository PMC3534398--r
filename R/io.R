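#' Write genotypes as PLINK-text .ped/.map files
#'
#' Genotypes coded -1/0/1 become allele pairs `A A`, `A B`, `B B`; missing
#' calls become `0 0`.  The .map file holds chromosome, marker name, a zero
#' genetic distance, and base-pair position.
#'
#' @param genotypes A [genotype_matrix()] with hard -1/0/1 calls.
#' @param prefix Output path prefix; `<prefix>.ped` and `<prefix>.map` are
#'   written.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(genotypes, prefix) {
  g <- genotypes$genotypes
  if (any(!is.na(g) & g != round(g)))
    stop("PLINK output requires hard -1/0/1 calls (write before imputation)")
  map <- genotypes$map
  utils::write.table(data.frame(map$chrom, map$marker, 0, map$pos),
                     paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  allele1 <- matrix("A", nrow(g), ncol(g))
  allele2 <- matrix("B", nrow(g), ncol(g))
  allele1[!is.na(g) & g == 1] <- "B"
  allele2[!is.na(g) & g == -1] <- "A"
  allele1[is.na(g)] <- "0"
  allele2[is.na(g)] <- "0"
  inter <- matrix("", nrow(g), 2 * ncol(g))
  inter[, seq(1, 2 * ncol(g), by = 2)] <- allele1
  inter[, seq(2, 2 * ncol(g), by = 2)] <- allele2
  ped <- cbind(genotypes$ids, genotypes$ids, 0, 0, 0, -9, inter)
  utils::write.table(ped, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK-text .ped/.map genotypes
#'
#' Allele letters are recoded to -1/0/1 by the minor-allele convention: at
#' each marker the rarer allele is the one counted positively, so +1 is the
#' minor-allele homozygote.  `0` alleles are treated as missing.
#'
#' @param prefix Path prefix of the `.ped`/`.map` pair.
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), sep = "\t",
                           col.names = c("chrom", "marker", "cm", "pos"),
                           stringsAsFactors = FALSE)
  ped <- utils::read.table(paste0(prefix, ".ped"), stringsAsFactors = FALSE,
                           colClasses = "character")
  p <- nrow(map)
  if (ncol(ped) != 6 + 2 * p)
    stop(".ped column count does not match the .map marker count")
  ids <- ped[[2]]
  a1 <- as.matrix(ped[, 6 + seq(1, 2 * p, by = 2), drop = FALSE])
  a2 <- as.matrix(ped[, 6 + seq(2, 2 * p, by = 2), drop = FALSE])
  geno <- matrix(NA_real_, nrow(ped), p)
  for (j in seq_len(p)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    alleles <- sort(unique(c(x1[!miss], x2[!miss])))
    if (length(alleles) == 0) next
    # count the rarer allele; ties broken by sort order for determinism
    counts <- vapply(alleles, function(a) sum(x1 == a) + sum(x2 == a), numeric(1))
    minor <- alleles[which.min(counts)]
    geno[, j] <- (x1 == minor) + (x2 == minor) - 1
    geno[miss, j] <- NA_real_
  }
  genotype_matrix(geno, data.frame(marker = map$marker, chrom = map$chrom,
                                   pos = map$pos), ids = ids)
}

#' Write / read a TSV genotype matrix
#'
#' The TSV dialect has animals in rows and markers in columns, an `id`
#' column first, and cells in -1/0/1 or `NA`.  The map travels in a
#' companion TSV with columns `marker`, `chrom`, `pos` (and optionally
#' `genic`).
#'
#' @param genotypes A [genotype_matrix()].
#' @param geno_path,map_path Output (or input) file paths.
#' @return `write_genotype_tsv`: `geno_path`, invisibly.
#'   `read_genotype_tsv`: a [genotype_matrix()].
#' @export
write_genotype_tsv <- function(genotypes, geno_path, map_path) {
  df <- data.frame(id = genotypes$ids, genotypes$genotypes,
                   check.names = FALSE)
  utils::write.table(df, geno_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(genotypes$map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(geno_path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(geno_path, map_path) {
  df <- utils::read.delim(geno_path, check.names = FALSE)
  map <- utils::read.delim(map_path)
  ids <- df$id
  g <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  if (!identical(colnames(g), as.character(map$marker)))
    stop("genotype columns and map markers do not match")
  genotype_matrix(g, map, ids = ids)
}

#' Write pedigree / proxy-record / QTL tables as TSV
#'
#' @param x The table to write (`pedigree`, proxy records with
#'   `id`/`trait`/`tbv`/`ebv`/`reliability`, or QTL intervals).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pedigree_tsv <- function(x, path) {
  utils::write.table(x[, c("id", "sire", "dam")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree_tsv
#' @export
write_proxy_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree_tsv
#' @export
write_qtl_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pedigree TSV (id, sire, dam)
#'
#' @param path TSV path with columns `id`, `sire`, `dam` (0 = unknown).
#' @return Pedigree data frame.
#' @export
read_pedigree_tsv <- function(path) {
  ped <- utils::read.delim(path)
  check_pedigree(ped)
  ped
}

#' Derive gene intervals from a simulated marker map and write them as GFF3
#'
#' Contiguous genic marker runs become gene features spanning the run's
#' base-pair range.  Written through `rtracklayer`, so the output is
#' standard GFF3 with `type = gene`.
#'
#' @param map Marker map with a logical `genic` column.
#' @param path Output `.gff3` path.
#' @return The `GRanges` written, invisibly.
#' @export
write_gene_gff3 <- function(map, path) {
  stopifnot("genic" %in% names(map))
  runs <- list()
  for (ch in unique(map$chrom)) {
    sub <- map[map$chrom == ch, , drop = FALSE]
    r <- rle(sub$genic)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      runs[[length(runs) + 1]] <- data.frame(
        chrom = ch, start = sub$pos[starts[k]], end = sub$pos[ends[k]])
    }
  }
  if (length(runs) == 0) {
    gr <- GenomicRanges::GRanges()
  } else {
    gdf <- do.call(rbind, runs)
    gr <- GenomicRanges::GRanges(as.character(gdf$chrom),
                                 IRanges::IRanges(gdf$start, gdf$end),
                                 type = "gene",
                                 ID = sprintf("gene%03d", seq_len(nrow(gdf))))
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(gr)
}
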