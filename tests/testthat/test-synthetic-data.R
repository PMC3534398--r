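test_that("pedigree simulation respects generation structure and counts", {
  cfg1 <- sim_config(n_founders = 10, n_generations = 1, seed = 3)
  ped1 <- simulate_pedigree(cfg1)
  expect_equal(nrow(ped1), 10)
  expect_true(all(ped1$sire == 0 & ped1$dam == 0))

  # offspring bookkeeping: matings per generation x offspring_per_mating
  cfg <- sim_config(n_founders = 20, n_generations = 2,
                    offspring_per_mating = 2, seed = 5)
  ped <- simulate_pedigree(cfg)
  n_matings <- 20 %/% 2
  expect_equal(sum(ped$generation == 2), n_matings * 2)
  expect_equal(nrow(ped), 20 + n_matings * 2)
  # parents precede offspring and are valid
  expect_silent(flowgwas:::check_pedigree(ped))

  # seeded determinism
  cfg2 <- sim_config(n_founders = 10, n_generations = 3, seed = 1)
  expect_identical(simulate_pedigree(cfg2), simulate_pedigree(cfg2))

  expect_error(sim_config(n_founders = 0, n_generations = 2), "founders")
})

test_that("marker map places sorted positions and genic blocks at the target fraction", {
  cfg0 <- sim_config(n_chromosomes = 29, markers_per_chromosome = 100,
                     gene_fraction = 0, seed = 2)
  map0 <- simulate_marker_map(cfg0)
  expect_equal(nrow(map0), 2900)
  expect_equal(length(unique(map0$chrom)), 29)
  expect_false(any(map0$genic))
  by_chr <- split(map0$pos, map0$chrom)
  expect_true(all(vapply(by_chr, function(x) all(diff(x) > 0), logical(1))))

  cfg3 <- sim_config(n_chromosomes = 10, markers_per_chromosome = 100,
                     gene_fraction = 0.30, seed = 2)
  map3 <- simulate_marker_map(cfg3)
  expect_lt(abs(mean(map3$genic) - 0.30), 0.05)
  # genic markers come in contiguous runs (mean run length > 1)
  runs <- rle(map3$genic)
  expect_gt(mean(runs$lengths[runs$values]), 1)

  expect_error(simulate_marker_map(
    sim_config(markers_per_chromosome = 50, chromosome_length = 10)),
    "too small")
})

test_that("gene dropping reproduces founder frequencies and parent-offspring transmission", {
  # founders only at fixed frequency 0.5: empirical MAF within binomial error
  cfg <- sim_config(n_founders = 500, n_generations = 1, n_chromosomes = 2,
                    markers_per_chromosome = 50, maf_range = c(0.5, 0.5),
                    seed = 11)
  ped <- simulate_pedigree(cfg)
  map <- simulate_marker_map(cfg)
  geno <- simulate_genotypes(ped, map, cfg)
  se <- sqrt(0.5 * 0.5 / (2 * 500))         # binomial se of an allele frequency
  expect_true(all(abs(geno$freq - 0.5) < 5 * se))
  expect_true(all(geno$genotypes %in% c(-1, 0, 1)))

  # forced transmission: offspring of two homozygous parents is homozygous
  ped2 <- data.frame(id = 1:3, sire = c(0L, 0L, 1L), dam = c(0L, 0L, 2L),
                     generation = c(1L, 1L, 2L))
  cfg2 <- sim_config(n_founders = 2, n_generations = 2, maf_range = c(0.05, 0.05),
                     n_chromosomes = 1, markers_per_chromosome = 30, seed = 1)
  found <- FALSE
  for (s in 1:20) {                          # find a marker fixed at -1 in both parents
    cfg2$seed <- s
    g <- simulate_genotypes(ped2, simulate_marker_map(cfg2), cfg2)
    fixed <- which(g$genotypes[1, ] == -1 & g$genotypes[2, ] == -1)
    if (length(fixed)) {
      expect_true(all(g$genotypes[3, fixed] == -1))
      found <- TRUE
      break
    }
  }
  expect_true(found)

  # parent-offspring genotype correlation across markers ~ 0.5
  cfg3 <- sim_config(n_founders = 200, n_generations = 2, n_chromosomes = 5,
                     markers_per_chromosome = 80, seed = 4)
  ped3 <- simulate_pedigree(cfg3)
  map3 <- simulate_marker_map(cfg3)
  g3 <- simulate_genotypes(ped3, map3, cfg3)
  kids <- which(ped3$sire != 0)
  gc3 <- sweep(g3$genotypes, 2, colMeans(g3$genotypes))  # remove MAF-driven means
  cors <- vapply(kids[1:100], function(i) {
    stats::cor(gc3[i, ], gc3[match(ped3$sire[i], ped3$id), ])
  }, numeric(1))
  expect_lt(abs(mean(cors) - 0.5), 0.05)

  expect_error(
    simulate_genotypes(data.frame(id = 1:2, sire = c(0L, 9L), dam = c(0L, 9L),
                                  generation = c(1L, 2L)),
                       map, cfg),
    "parent ids")
})

test_that("planted QTL effects satisfy the variance identity exactly", {
  pop <- small_population(seed = 9)
  eff <- pop$effects
  qtl <- attr(eff, "qtl_idx")
  expect_length(qtl, 4)
  expect_true(all(eff[-qtl] == 0))
  q <- pop$genotypes$freq
  v <- sum(eff^2 * 2 * q * (1 - q))
  target <- 0.4 * 0.35 * 1
  expect_lt(abs(v - target), 1e-10)

  # n_qtl = 0 -> all zero; same seed -> identical
  cfg0 <- sim_config(n_qtl = 0, seed = 2)
  pop0 <- small_population(seed = 2, n_qtl = 0)
  expect_true(all(pop0$effects == 0))
  eff2 <- plant_qtl(pop$map, pop$genotypes, pop$config)
  expect_identical(eff, eff2)
})

test_that("EBV proxies have the configured accuracy structure", {
  # reliability 1 -> EBV == TBV
  pop1 <- small_population(seed = 3, reliability_range = c(1, 1))
  expect_equal(pop1$proxies$ebv, pop1$proxies$tbv, tolerance = 1e-10)

  # reliability 0.49 across many animals -> cor^2(EBV, TBV) ~ 0.49
  cfg <- sim_config(n_founders = 2000, n_generations = 1, n_chromosomes = 2,
                    markers_per_chromosome = 30, n_qtl = 5,
                    reliability_range = c(0.49, 0.49), seed = 8)
  pop <- simulate_population(cfg)
  r2 <- stats::cor(pop$proxies$ebv, pop$proxies$tbv)^2
  expect_lt(abs(r2 - 0.49), 0.05)

  # no genetic variance -> TBV identically zero
  popz <- small_population(seed = 5, h2 = 0, n_qtl = 0)
  expect_true(all(popz$proxies$tbv == 0))
})

test_that("simulated populations satisfy relationship and variance bookkeeping", {
  cfg <- sim_config(n_founders = 400, n_generations = 3, n_chromosomes = 6,
                    markers_per_chromosome = 100, n_qtl = 10, h2 = 0.35,
                    seed = 21)
  pop <- simulate_population(cfg)
  A <- build_numerator_relationship(pop$pedigree)

  # genomic relationship of parent-offspring pairs matches A within 0.1
  W <- scale(pop$genotypes$genotypes)
  G <- tcrossprod(W) / ncol(W)
  kids <- which(pop$pedigree$sire != 0)[1:150]
  sire_row <- match(pop$pedigree$sire[kids], pop$pedigree$id)
  g_po <- mean(G[cbind(kids, sire_row)])
  a_po <- mean(A[cbind(kids, sire_row)])
  expect_lt(abs(g_po - a_po), 0.1)
  # and unrelated founder pairs sit near 0
  f <- which(pop$pedigree$generation == 1)
  expect_lt(abs(mean(G[f[1:100], f[101:200]])), 0.1)

  # full-run determinism, bit identical
  pop2 <- simulate_population(cfg)
  expect_identical(pop$genotypes$genotypes, pop2$genotypes$genotypes)
  expect_identical(pop$proxies, pop2$proxies)

  # TBV variance across >= 1000 final-generation animals ~ h2 * Vp within 15%
  cfgv <- sim_config(n_founders = 1000, n_generations = 3, n_chromosomes = 4,
                     markers_per_chromosome = 75, n_qtl = 10, h2 = 0.35,
                     seed = 22)
  popv <- simulate_population(cfgv)
  last <- popv$proxies$tbv[popv$pedigree$generation == 3]
  expect_gte(length(last), 1000)
  expect_lt(abs(stats::var(last) - 0.35) / 0.35, 0.15)
})
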