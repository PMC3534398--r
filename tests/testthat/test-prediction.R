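test_that("reliability split uses a strict threshold per record", {
  rec <- data.frame(id = 1:3, reliability = c(0.61, 0.60, 0.59))
  sp <- split_by_reliability(rec, 0.60)
  expect_equal(sp$discovery, 1)
  expect_equal(sp$prediction, c(2, 3))

  # everyone reliable: empty prediction set is flagged
  expect_warning(split_by_reliability(
    data.frame(id = 1:4, reliability = rep(0.8, 4)), 0.60), "empty")
  # nobody reliable: hard error
  expect_error(split_by_reliability(
    data.frame(id = 1:4, reliability = rep(0.5, 4)), 0.60), "discovery")

  # reliabilities drawn in the study range are prediction-heavy and reconcile
  pop <- small_population(seed = 77, reliability_range = c(0.38, 0.70))
  sp2 <- split_by_reliability(pop$proxies, 0.60)
  expect_equal(length(sp2$discovery) + length(sp2$prediction),
               nrow(pop$proxies))
  expect_gt(length(sp2$prediction), length(sp2$discovery))
  expect_equal(sort(c(sp2$discovery, sp2$prediction)), sort(pop$proxies$id))
})

test_that("direct genomic values are linear, additive and exactly decomposable", {
  geno <- toy_genotypes(matrix(c(-1, 0, 1), 3, 1))
  expect_equal(unname(compute_dgv(geno, c(m1 = 0.5))), c(-0.5, 0, 0.5))
  expect_equal(unname(compute_dgv(geno, c(m1 = 0))), c(0, 0, 0))

  pop <- small_population(seed = 78)
  g <- pop$genotypes
  set.seed(79)
  beta <- rnorm(ncol(g$genotypes), 0, 0.1)
  names(beta) <- g$map$marker
  subset <- sample(names(beta), 30)
  complement <- setdiff(names(beta), subset)
  # additivity over a subset and its complement, exact to IEEE round-off
  expect_equal(compute_dgv(g, beta),
               compute_dgv(g, beta, subset) +
                 compute_dgv(g, beta, complement),
               tolerance = 1e-12)
  # empty subset gives identically zero DGVs
  expect_true(all(compute_dgv(g, beta, character(0)) == 0))
  expect_error(compute_dgv(g, beta, "nope"), "not present")
})

test_that("correlation recovery and variance proportions behave on nested subsets", {
  geno <- le_panel(600, 500, maf = 0.3, seed = 80)
  set.seed(81)
  beta <- rnorm(500, 0, 0.05)
  names(beta) <- geno$map$marker
  dt <- dgv_table(geno, beta, subsets = c(25, 50, 100, 300))
  expect_equal(colnames(dt), c("25", "50", "100", "300", "all"))

  # EBV equal to the full DGV: correlation and recovery exactly 1
  ebv <- dt[, "all"]
  rec <- correlation_recovery(ebv, dt)
  expect_equal(rec$correlation[rec$subset == "all"], 1)
  expect_equal(rec$recovery[rec$subset == "all"], 1)

  gv <- genomic_variance_proportions(dt)
  expect_equal(gv$proportion[gv$subset == "all"], 1)
  # under linkage equilibrium the nested-subset proportions are monotone
  expect_true(all(diff(gv$proportion) >= 0))
  expect_true(all(gv$proportion >= 0 & gv$proportion <= 1 + 1e-12))

  expect_error(correlation_recovery(ebv[1:2], dt[1:2, ]), "at least 3")
})

test_that("the recovery curve saturates before the full panel", {
  # mostly-polygenic architecture: many small effects, a few moderate QTL
  geno <- le_panel(800, 600, maf = 0.3, seed = 82)
  set.seed(83)
  beta_true <- rnorm(600, 0, 0.02)
  beta_true[sample(600, 10)] <- rnorm(10, 0, 0.15)
  g <- as.vector(geno$genotypes %*% beta_true)
  ebv <- g + rnorm(800, 0, sd(g))          # noisy proxy of the genetic merit
  names(ebv) <- geno$ids
  beta_hat <- beta_true + rnorm(600, 0, 0.01)   # estimation noise
  names(beta_hat) <- geno$map$marker
  dt <- dgv_table(geno, beta_hat, subsets = c(30, 100, 300, 500))
  rec <- correlation_recovery(ebv, dt)
  r <- setNames(rec$recovery, rec$subset)
  expect_gt(r[["300"]] - r[["100"]], r[["all"]] - r[["300"]])
  expect_true(all(diff(setNames(rec$correlation, NULL)) > -0.02))
})

test_that("prediction-set DGVs track true merit better than a permuted-effect baseline", {
  wins <- 0L
  for (rep in 1:5) {
    pop <- small_population(seed = 90 + rep, n_founders = 100,
                            n_generations = 3, n_chromosomes = 4,
                            markers_per_chromosome = 25, n_qtl = 6,
                            qtl_variance = 0.5, h2 = 0.4,
                            reliability_range = c(0.38, 0.9))
    qc <- apply_filters(pop$genotypes)
    dr <- deregress_records(pop$proxies, pop$pedigree, h2 = 0.4)
    sp <- split_by_reliability(pop$proxies, 0.60)
    disc <- pop$proxies$id %in% sp$discovery & !dr$flagged & !is.na(dr$drp)
    gd <- qc$genotypes
    y <- dr$drp[disc]
    gdisc <- genotype_matrix(gd$genotypes[disc, , drop = FALSE], gd$map,
                             ids = gd$ids[disc])
    fit <- run_gibbs(y, gdisc, NULL,
                     blasso_control(niter = 1500, burnin = 500, thin = 2,
                                    lambda = 10, seed = rep))
    pred <- pop$proxies$id %in% sp$prediction
    gpred <- genotype_matrix(gd$genotypes[pred, , drop = FALSE], gd$map,
                             ids = gd$ids[pred])
    dgv <- compute_dgv(gpred, fit$beta_mean)
    set.seed(rep)
    dgv_null <- compute_dgv(gpred, sample(fit$beta_mean))
    tbv <- pop$proxies$tbv[pred]
    if (cor(dgv, tbv) > cor(dgv_null, tbv)) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("gene-region flagging respects the 500-kb flank", {
  map <- data.frame(marker = c("m1", "m2", "m3"), chrom = c(1L, 1L, 2L),
                    pos = c(600000L, 2000000L, 600000L))
  genes <- data.frame(chrom = 1L, start = 1000000L, end = 1200000L)
  # m1 is 400 kb upstream (inside the flank), m2 800 kb downstream (outside),
  # m3 on another chromosome
  fl <- flag_gene_region_markers(map, genes, flank = 5e5)
  expect_equal(unname(fl), c(TRUE, FALSE, FALSE))
  fl2 <- flag_gene_region_markers(map, genes, flank = 3e5)
  expect_equal(unname(fl2), c(FALSE, FALSE, FALSE))  # 400 kb now outside too
  # marker 600 kb from every gene is never flagged at the default flank
  genes2 <- data.frame(chrom = 1L, start = 2600000L, end = 2700000L)
  expect_false(flag_gene_region_markers(map, genes2)[["m1"]])
  # empty gene set or mismatching chromosome names: zero flags
  expect_false(any(flag_gene_region_markers(map, genes[0, ])))
  expect_warning(
    fl3 <- flag_gene_region_markers(map, data.frame(chrom = "chrX",
                                                    start = 1, end = 10)),
    "chromosome")
  expect_false(any(fl3))
})

test_that("genic DGV proportion matches a planted variance split", {
  # identical sets: every ratio is 1
  d <- rnorm(50) + 1
  expect_equal(gene_dgv_proportion(d, d)$proportion, 1)
  # zero genic effects: median 0
  expect_equal(gene_dgv_proportion(rep(0, 50), d)$proportion, 0)

  # genic markers carrying 50% of the significant-marker variance
  # mean-zero panel (MAF 0.5) so the DGV location does not dominate ratios
  geno <- le_panel(4000, 200, maf = 0.5, seed = 85)
  set.seed(86)
  beta <- rnorm(200, 0, 0.1)
  names(beta) <- geno$map$marker
  genic <- geno$map$marker[1:100]
  # rescale the genic half so it carries exactly 50% of the DGV variance
  v <- apply(geno$genotypes, 2, var)
  beta[1:100] <- beta[1:100] *
    sqrt(sum(beta[101:200]^2 * v[101:200]) / sum(beta[1:100]^2 * v[1:100]))
  dgv_sig <- compute_dgv(geno, beta)
  dgv_gene <- compute_dgv(geno, beta, genic)
  res <- gene_dgv_proportion(dgv_gene, dgv_sig)
  expect_lt(abs(res$proportion - 0.5), 0.1)
  vr <- gene_dgv_proportion(dgv_gene, dgv_sig, method = "variance_ratio")
  expect_lt(abs(vr$proportion - 0.5), 0.1)
})
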