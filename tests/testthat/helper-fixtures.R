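# Shared in-code fixtures for the test suite.

# Small multi-generation population with planted QTL.
small_population <- function(seed = 7, n_founders = 60, n_generations = 3,
                             n_chromosomes = 5, markers_per_chromosome = 20,
                             n_qtl = 4, qtl_variance = 0.4, h2 = 0.35, ...) {
  cfg <- sim_config(n_founders = n_founders, n_generations = n_generations,
                    n_chromosomes = n_chromosomes,
                    markers_per_chromosome = markers_per_chromosome,
                    n_qtl = n_qtl, qtl_variance = qtl_variance, h2 = h2,
                    seed = seed, ...)
  simulate_population(cfg)
}

# Genotype matrix built directly from a code matrix, with a default map.
toy_genotypes <- function(codes, chrom = NULL, pos = NULL) {
  codes <- as.matrix(codes)
  p <- ncol(codes)
  map <- data.frame(marker = paste0("m", seq_len(p)),
                    chrom = chrom %||% rep(1L, p),
                    pos = pos %||% seq_len(p) * 1000L)
  genotype_matrix(codes, map)
}

# Unstructured marker panel in linkage equilibrium (founders only).
le_panel <- function(n, p, maf = 0.3, seed = 1) {
  set.seed(seed)
  g <- matrix(stats::rbinom(n * p, 2, maf) - 1, n, p)
  toy_genotypes(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
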