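#' Numerator relationship matrix by the tabular method
#'
#' Computes the pedigree-expected additive relationship matrix A over the
#' full pedigree by the tabular recursion (`a_ij = 0.5 (a_{i,sire(j)} +
#' a_{i,dam(j)})`, `a_jj = 1 + 0.5 a_{sire(j),dam(j)}`), then restricts it to
#' the requested animal subset, so ancestral ties among subset members are
#' preserved.
#'
#' @param pedigree Data frame with columns `id`, `sire`, `dam`; parents must
#'   precede offspring (0 = unknown).
#' @param ids Optional animal ids to restrict to (default: all).
#' @return Dense symmetric matrix with `ids` as dimnames.
#' @export
build_numerator_relationship <- function(pedigree, ids = NULL) {
  check_pedigree(pedigree)
  n <- nrow(pedigree)
  pos <- seq_len(n)
  sp <- match(pedigree$sire, pedigree$id)
  dp <- match(pedigree$dam, pedigree$id)
  A <- matrix(0, n, n)
  for (i in pos) {
    s <- sp[i]; d <- dp[i]
    if (i > 1) {
      prev <- seq_len(i - 1L)
      row_i <- numeric(i - 1L)
      if (!is.na(s)) row_i <- row_i + 0.5 * A[s, prev]
      if (!is.na(d)) row_i <- row_i + 0.5 * A[d, prev]
      A[i, prev] <- row_i
      A[prev, i] <- row_i
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(pedigree$id, pedigree$id)
  if (!is.null(ids)) {
    idx <- match(as.character(ids), as.character(pedigree$id))
    if (anyNA(idx)) stop("subset ids not present in pedigree")
    A <- A[idx, idx, drop = FALSE]
  }
  A
}

#' Bayesian LASSO chain configuration
#'
#' Defaults follow the long-chain protocol used for sire-GWAS analyses of
#' this kind: a single chain of 100,000 iterations with 30,000 burn-in and
#' every 30th sample stored, the shrinkage parameter lambda fixed in the
#' final run from the average of 5 exploratory chains of 50,000 iterations
#' in which lambda-squared is sampled under a diffuse gamma prior.
#'
#' @param niter Chain length in iterations.
#' @param burnin Burn-in iterations (discarded).
#' @param thin Storage interval.
#' @param lambda Fixed shrinkage parameter; `NULL` means sample it (or call
#'   [estimate_lambda()] first).
#' @param lambda_shape,lambda_rate Gamma hyperprior on lambda-squared used
#'   when lambda is sampled.
#' @param n_exploratory,exploratory_iter Number and length of exploratory
#'   chains used by [estimate_lambda()].
#' @param df_e,scale_e Scaled-inverse-chi-square prior on the residual
#'   variance; `scale_e = NULL` sets the scale from the data variance.
#' @param df_s,scale_s Same for the polygenic variance.
#' @param fix_mu Fix the overall mean at 0 (for pre-centred responses).
#' @param fix_sigma2e Numeric value to hold the residual variance at, or
#'   `NULL` to sample it.
#' @param seed Integer seed for the chain.
#' @return List of class `blasso_control`.
#' @export
blasso_control <- function(niter = 100000, burnin = 30000, thin = 30,
                           lambda = NULL, lambda_shape = 0.1, lambda_rate = 0.1,
                           n_exploratory = 5, exploratory_iter = 50000,
                           df_e = 4, scale_e = NULL, df_s = 4, scale_s = NULL,
                           fix_mu = FALSE, fix_sigma2e = NULL, seed = 1L) {
  stopifnot(burnin < niter, thin >= 1, niter >= 1)
  if (!is.null(lambda) && lambda <= 0) stop("lambda must be positive")
  structure(list(niter = as.integer(niter), burnin = as.integer(burnin),
                 thin = as.integer(thin), lambda = lambda,
                 lambda_shape = lambda_shape, lambda_rate = lambda_rate,
                 n_exploratory = as.integer(n_exploratory),
                 exploratory_iter = as.integer(exploratory_iter),
                 df_e = df_e, scale_e = scale_e, df_s = df_s,
                 scale_s = scale_s, fix_mu = isTRUE(fix_mu),
                 fix_sigma2e = fix_sigma2e, seed = as.integer(seed)),
            class = "blasso_control")
}

# Shared data preparation for the samplers: aligns y / genotypes / A,
# centres, eigendecomposes A.  Returns the pieces the C++ code needs.
prepare_model_inputs <- function(y, genotypes, A, control) {
  if (inherits(genotypes, "genotype_matrix")) {
    X <- genotypes$genotypes
    map <- genotypes$map
  } else {
    X <- as.matrix(genotypes)
    nm <- colnames(X) %||% sprintf("m%d", seq_len(ncol(X)))
    map <- data.frame(marker = nm, chrom = rep(1L, ncol(X)),
                      pos = seq_len(ncol(X)))
  }
  if (anyNA(X)) stop("genotypes contain missing values; run apply_filters() first")
  n <- length(y)
  if (nrow(X) != n) stop("y and genotypes must cover the same animals, in order")
  use_poly <- !is.null(A)
  U <- matrix(0, 0, 0); dvals <- numeric(0)
  if (use_poly) {
    A <- as.matrix(A)
    if (nrow(A) != n || ncol(A) != n)
      stop("A must be square over the same animals as y")
    if (max(abs(A - t(A))) > 1e-8) stop("A must be symmetric")
    eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
    dvals <- pmax(eg$values, 0)
    if (min(eg$values) < -1e-6 * max(dvals))
      stop("A is not positive semidefinite")
    U <- eg$vectors
  }
  Xc <- sweep(X, 2, colMeans(X))               # column-centred genotypes
  vy <- stats::var(y)
  scale_e <- control$scale_e %||% max(vy * 0.5, 1e-8)
  scale_s <- control$scale_s %||% max(vy * 0.25, 1e-8)
  list(y = as.numeric(y), X = Xc, map = map, use_poly = use_poly, U = U,
       d = dvals, scale_e = scale_e, scale_s = scale_s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the Bayesian LASSO marker-regression model by Gibbs sampling
#'
#' Samples the joint posterior of the model `y = mu + S + X beta + e` with
#' `beta_j | tau2_j ~ N(0, tau2_j sigma2_e)`, `tau2_j ~ Exp(lambda^2 / 2)`
#' (so marginally each marker effect has a double-exponential prior),
#' `S ~ N(0, A sigma2_s)` and `e ~ N(0, I sigma2_e)`.  All markers are
#' fitted simultaneously.  The response is centred and genotype columns are
#' mean-centred internally; neither affects the marker-effect posterior.
#'
#' @param y Numeric response (de-regressed proofs), one record per animal.
#' @param genotypes A [genotype_matrix()] (QC-filtered, no missing values)
#'   or a plain numeric matrix.
#' @param A Numerator relationship matrix over the same animals, or `NULL`
#'   to omit the polygenic effect.
#' @param control A [blasso_control()].  `control$lambda` must be set (fix it
#'   via [estimate_lambda()] or supply it directly); if `NULL`, lambda is
#'   sampled under its gamma hyperprior.
#' @return Object of class `blasso_fit`: per-marker posterior means and SDs,
#'   stored sample matrices for `beta`, `mu`, `sigma2e`, `sigma2s`,
#'   `lambda`, effective sample sizes for the variances, and the marker map.
#' @export
run_gibbs <- function(y, genotypes, A = NULL, control = blasso_control()) {
  stopifnot(inherits(control, "blasso_control"))
  inp <- prepare_model_inputs(y, genotypes, A, control)
  sample_lambda <- is.null(control$lambda)
  lambda0 <- if (sample_lambda) sqrt(control$lambda_shape / control$lambda_rate)
             else control$lambda
  set.seed(control$seed)
  raw <- .blasso_gibbs_cpp(inp$y, inp$X, inp$use_poly, inp$U, inp$d,
                           control$niter, control$burnin, control$thin,
                           lambda0, sample_lambda,
                           control$lambda_shape, control$lambda_rate,
                           control$df_e, inp$scale_e,
                           !is.null(control$fix_sigma2e),
                           control$fix_sigma2e %||% 0,
                           control$df_s, inp$scale_s,
                           control$fix_mu, 0L)
  finish_blasso_fit(raw, inp, control, permuted = FALSE)
}

finish_blasso_fit <- function(raw, inp, control, permuted, perm = NULL) {
  beta <- raw$beta
  rownames(beta) <- inp$map$marker
  s2e <- as.numeric(raw$sigma2e)
  s2s <- as.numeric(raw$sigma2s)
  fit <- list(beta_mean = rowMeans(beta),
              beta_sd = apply(beta, 1, stats::sd),
              beta_samples = beta,
              mu_samples = as.numeric(raw$mu),
              sigma2e_samples = s2e,
              sigma2s_samples = s2s,
              lambda_samples = as.numeric(raw$lambda),
              ess = c(sigma2e = chain_ess(s2e),
                      sigma2s = if (inp$use_poly) chain_ess(s2s) else NA_real_),
              map = inp$map, control = control, permuted = permuted,
              perm_control = perm, n_animals = length(inp$y))
  class(fit) <- if (permuted) c("blasso_null", "blasso_fit") else "blasso_fit"
  fit
}

#' @export
print.blasso_fit <- function(x, ...) {
  cat(if (x$permuted) "within-chain-permutation null" else "Bayesian LASSO",
      "fit:", length(x$beta_mean), "markers,", x$n_animals, "animals,",
      ncol(x$beta_samples), "stored samples\n")
  cat(sprintf("  posterior means: sigma2_e = %.4g, lambda = %.4g\n",
              mean(x$sigma2e_samples), mean(x$lambda_samples)))
  invisible(x)
}

#' Fix the shrinkage parameter from exploratory chains
#'
#' Runs several shorter chains in which lambda-squared is sampled from its
#' full conditional under a gamma hyperprior, and returns the average of the
#' chains' posterior means of lambda.  A crude convergence screen flags the
#' result (without withholding it) when the chains disagree strongly or the
#' lambda chains barely move.
#'
#' @param y,genotypes,A As in [run_gibbs()].
#' @param control A [blasso_control()]; `n_exploratory` and
#'   `exploratory_iter` govern the chains, `lambda_shape`/`lambda_rate` the
#'   hyperprior.
#' @return List with `lambda` (the average), `per_chain` (posterior means),
#'   `flagged` (convergence warning indicator).
#' @export
estimate_lambda <- function(y, genotypes, A = NULL,
                            control = blasso_control()) {
  stopifnot(inherits(control, "blasso_control"), control$n_exploratory >= 1)
  per_chain <- numeric(control$n_exploratory)
  ess <- numeric(control$n_exploratory)
  for (k in seq_len(control$n_exploratory)) {
    ctl <- control
    ctl$lambda <- NULL
    ctl$niter <- control$exploratory_iter
    ctl$burnin <- min(control$burnin, control$exploratory_iter %/% 3)
    ctl$seed <- control$seed + 1000L * k
    fit <- run_gibbs(y, genotypes, A, ctl)
    per_chain[k] <- mean(fit$lambda_samples)
    ess[k] <- chain_ess(fit$lambda_samples)
  }
  lambda <- mean(per_chain)
  cv <- stats::sd(per_chain) / lambda
  flagged <- (length(per_chain) > 1 && is.finite(cv) && cv > 0.5) ||
    any(ess < 10)
  if (flagged)
    warning("exploratory lambda chains failed the convergence screen ",
            "(cv = ", signif(cv, 3), "); the averaged value is returned anyway")
  list(lambda = lambda, per_chain = per_chain, flagged = flagged)
}

# Autocorrelation-based effective sample size of a scalar chain (spectral
# density at frequency zero from an AR fit, as coda does).
chain_ess <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) return(NA_real_)
  if (stats::var(x) == 0) return(n)            # degenerate constant chain
  as.numeric(coda::effectiveSize(coda::mcmc(x)))
}

#' Summarize a matrix or vector of stored posterior samples
#'
#' Posterior means and standard deviations per parameter, plus an
#' autocorrelation-based effective sample size.  A constant chain is
#' reported with SD 0, ESS equal to the stored-sample count, and a
#' degeneracy flag.
#'
#' @param samples Numeric vector (one parameter) or matrix with parameters
#'   in rows and stored samples in columns.
#' @return Data frame with columns `parameter`, `mean`, `sd`, `ess`,
#'   `degenerate`.
#' @export
summarize_posterior <- function(samples) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  if (ncol(samples) < 2) stop("at least 2 stored samples are required")
  nm <- rownames(samples) %||% paste0("param", seq_len(nrow(samples)))
  means <- rowMeans(samples)
  sds <- apply(samples, 1, stats::sd)
  ess <- vapply(seq_len(nrow(samples)), function(i) chain_ess(samples[i, ]),
                numeric(1))
  data.frame(parameter = nm, mean = means, sd = sds, ess = ess,
             degenerate = sds == 0, row.names = NULL)
}

#' Stored-sample count for a chain protocol
#'
#' @param niter,burnin,thin Chain protocol.
#' @return `floor((niter - burnin) / thin)`.
#' @export
n_stored_samples <- function(niter, burnin, thin) {
  stopifnot(burnin < niter, thin >= 1)
  as.integer((niter - burnin) %/% thin)
}
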