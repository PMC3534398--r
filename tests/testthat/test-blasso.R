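test_that("tabular relationship matrix reproduces textbook values", {
  # unrelated founders -> identity
  ped0 <- data.frame(id = 1:4, sire = 0L, dam = 0L, generation = 1L)
  expect_equal(unname(build_numerator_relationship(ped0)), diag(4))

  # parent-offspring with unrelated parents -> off-diagonal 0.5
  ped1 <- data.frame(id = 1:3, sire = c(0L, 0L, 1L), dam = c(0L, 0L, 2L),
                     generation = c(1L, 1L, 2L))
  A1 <- build_numerator_relationship(ped1)
  expect_equal(A1["3", "1"], 0.5)
  expect_equal(A1["3", "3"], 1)

  # offspring of a half-sib mating: a = 1 + 0.5 * 0.25 = 1.125
  ped2 <- data.frame(id = 1:6,
                     sire = c(0L, 0L, 0L, 1L, 1L, 4L),
                     dam = c(0L, 0L, 0L, 2L, 3L, 5L),
                     generation = c(1L, 1L, 1L, 2L, 2L, 3L))
  A2 <- build_numerator_relationship(ped2)
  expect_equal(A2["4", "5"], 0.25)
  expect_equal(A2["6", "6"], 1.125)

  # subsetting preserves ancestral ties
  As <- build_numerator_relationship(ped2, ids = c(4, 5, 6))
  expect_equal(As["4", "5"], 0.25)
  expect_equal(dim(As), c(3L, 3L))
  expect_error(build_numerator_relationship(ped2, ids = 99), "not present")
})

test_that("intercept-only model recovers the response mean", {
  set.seed(3)
  n <- 40
  y <- rep(2.5, n) + rnorm(n, 0, 0.01)
  A <- diag(n)
  ctl <- blasso_control(niter = 4000, burnin = 1000, thin = 2, lambda = 10,
                        seed = 5)
  fit <- run_gibbs(y, matrix(numeric(0), n, 0), A, ctl)
  expect_lt(abs(mean(fit$mu_samples) - mean(y)), 0.02)
})

test_that("single-marker posterior mean matches 2-D quadrature of the exact posterior", {
  set.seed(42)
  n <- 20; lambda <- 8; s2e <- 1.5
  x <- rnorm(n); x <- x - mean(x)
  y <- x * 0.8 + rnorm(n, 0, sqrt(s2e)); y <- y - mean(y)

  # independent oracle: grid quadrature over (beta, log tau2) of
  # N(y; x b, s2e I) N(b; 0, t2 s2e) Exp(t2; lambda^2/2)
  bgrid <- seq(-2, 3, length.out = 601)
  ugrid <- seq(-14, 6, length.out = 601)
  sse <- vapply(bgrid, function(b) sum((y - x * b)^2), numeric(1))
  M <- matrix(0, length(bgrid), length(ugrid))
  for (j in seq_along(ugrid)) {
    t2 <- exp(ugrid[j])
    M[, j] <- -sse / (2 * s2e) - 0.5 * log(t2 * s2e) -
      bgrid^2 / (2 * t2 * s2e) - lambda^2 * t2 / 2 + ugrid[j]
  }
  M <- exp(M - max(M))
  w <- rowSums(M)
  mean_quad <- sum(bgrid * w) / sum(w)

  ctl <- blasso_control(niter = 60000, burnin = 5000, thin = 5,
                        lambda = lambda, fix_mu = TRUE, fix_sigma2e = s2e,
                        seed = 11)
  fit <- run_gibbs(y, matrix(x, ncol = 1), A = NULL, ctl)
  expect_lt(abs(fit$beta_mean - mean_quad), 0.02)
})

test_that("larger lambda shrinks marker effects harder", {
  geno <- le_panel(50, 20, maf = 0.3, seed = 9)
  set.seed(10)
  y <- geno$genotypes %*% rnorm(20, 0, 0.2) + rnorm(50)
  base <- blasso_control(niter = 3000, burnin = 1000, thin = 2, seed = 7)
  f5 <- run_gibbs(y, geno, NULL, modifyList(base, list(lambda = 5)))
  f200 <- run_gibbs(y, geno, NULL, modifyList(base, list(lambda = 200)))
  expect_lt(mean(abs(f200$beta_mean)), mean(abs(f5$beta_mean)))
})

test_that("with no markers the residual variance follows its conjugate update", {
  set.seed(8)
  n <- 60; nu_e <- 4
  y <- rnorm(n, 0, sqrt(2)); y <- y - mean(y)
  scale_e <- 1.2
  ctl <- blasso_control(niter = 30000, burnin = 2000, thin = 2, lambda = 10,
                        fix_mu = TRUE, scale_e = scale_e, seed = 13)
  fit <- run_gibbs(y, matrix(numeric(0), n, 0), NULL, ctl)
  # closed form: sigma2_e ~ (nu S + y'y) / chisq(nu + n)
  df <- nu_e + n
  ss <- nu_e * scale_e + sum(y^2)
  expect_lt(abs(mean(fit$sigma2e_samples) - ss / (df - 2)) / (ss / (df - 2)), 0.05)
  th_q <- ss / qchisq(c(0.75, 0.25), df)
  emp_q <- quantile(fit$sigma2e_samples, c(0.25, 0.75), names = FALSE)
  expect_equal(emp_q, th_q, tolerance = 0.05)
})

test_that("with one record per sire and A = I the variance sum stays identified", {
  set.seed(14)
  n <- 800
  y <- rnorm(n, 0, sqrt(2))
  total <- stats::var(y)       # the realized variance is what the data inform
  ctl <- blasso_control(niter = 6000, burnin = 2000, thin = 4, lambda = 50,
                        seed = 15)
  fit <- run_gibbs(y, matrix(numeric(0), n, 0), diag(n), ctl)
  est <- mean(fit$sigma2e_samples + fit$sigma2s_samples)
  expect_lt(abs(est - total) / total, 0.10)
})

test_that("exploratory chains estimate lambda and react to signal strength", {
  geno <- le_panel(150, 60, maf = 0.3, seed = 20)
  set.seed(21)
  # strong marker signal vs pure noise with the same phenotypic variance
  b <- numeric(60); b[1:6] <- 0.35
  g_signal <- as.vector(geno$genotypes %*% b)
  y_sig <- g_signal + rnorm(150, 0, sqrt(max(1 - var(g_signal), 0.2)))
  y_noise <- rnorm(150, 0, sd(y_sig))
  ctl <- blasso_control(n_exploratory = 3, exploratory_iter = 3000,
                        burnin = 1000, thin = 2, seed = 22)
  est_sig <- estimate_lambda(y_sig, geno, NULL, ctl)
  est_noise <- estimate_lambda(y_noise, geno, NULL, ctl)
  expect_equal(est_sig$lambda, mean(est_sig$per_chain))
  expect_gt(est_noise$lambda, est_sig$lambda)

  # the default configuration mirrors the long-chain protocol
  def <- blasso_control()
  expect_equal(def$n_exploratory, 5L)
  expect_equal(def$exploratory_iter, 50000L)
  expect_equal(def$niter, 100000L)
  expect_equal(def$burnin, 30000L)
  expect_equal(def$thin, 30L)
})

test_that("posterior summaries report means, SDs and effective sample sizes", {
  # iid chain: ESS close to the sample count
  set.seed(30)
  s <- summarize_posterior(rnorm(1000))
  expect_lt(abs(s$ess - 1000), 200)
  expect_false(s$degenerate)

  # constant chain: SD 0, ESS = n, degeneracy flag
  s0 <- summarize_posterior(rep(1.3, 50))
  expect_equal(s0$sd, 0)
  expect_equal(s0$ess, 50)
  expect_true(s0$degenerate)
  expect_error(summarize_posterior(1.0), "at least 2")

  # stored-sample bookkeeping for the reference protocol
  expect_equal(n_stored_samples(100000, 30000, 30), 2333)
})

test_that("chains are bit-identical under a fixed seed and reject bad inputs", {
  geno <- le_panel(30, 10, seed = 31)
  set.seed(32)
  y <- rnorm(30)
  ctl <- blasso_control(niter = 500, burnin = 100, thin = 2, lambda = 15,
                        seed = 33)
  f1 <- run_gibbs(y, geno, NULL, ctl)
  f2 <- run_gibbs(y, geno, NULL, ctl)
  expect_identical(f1$beta_samples, f2$beta_samples)
  expect_identical(f1$sigma2e_samples, f2$sigma2e_samples)

  expect_error(blasso_control(lambda = -1), "positive")
  badA <- matrix(c(1, 2, 2, 1), 2, 2)        # indefinite
  expect_error(run_gibbs(rnorm(2), matrix(0, 2, 1), badA, ctl),
               "positive semidefinite")
  expect_error(run_gibbs(rnorm(3), geno, NULL, ctl), "same animals")
})
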