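#' Within-chain permutation configuration
#'
#' Settings for the within-chain permutation null of Che and Xu: the
#' response is reshuffled against the genotype rows every `h` iterations of
#' a dedicated Markov chain, and the stored marker-effect draws form the
#' null posterior from which percentile critical values are read.  `h = L`
#' is equivalent to across-chain permutation; `h = 1` permutes at every
#' iteration.  Defaults follow the protocol used for this style of sire
#' GWAS: `h = 3` and a 250,000-iteration permuted chain.
#'
#' @param h Reshuffle interval in iterations, `1 <= h <= niter`.
#' @param niter Permuted-chain length.
#' @param burnin Burn-in iterations for the permuted chain.
#' @param thin Storage interval.
#' @param alpha Significance level for [critical_values()].
#' @param scope `"per_marker"` (each marker's own null draws) or `"pooled"`
#'   (all markers' draws pooled into one null).
#' @param seed Integer seed.
#' @return List of class `perm_control`.
#' @export
perm_control <- function(h = 3, niter = 250000, burnin = 30000, thin = 30,
                         alpha = 0.05, scope = c("per_marker", "pooled"),
                         seed = 1L) {
  scope <- match.arg(scope)
  stopifnot(h >= 1, h <= niter, burnin < niter, thin >= 1,
            alpha > 0, alpha < 1)
  structure(list(h = as.integer(h), niter = as.integer(niter),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 alpha = alpha, scope = scope, seed = as.integer(seed)),
            class = "perm_control")
}

#' Run the within-chain permutation null chain
#'
#' Runs the same Gibbs sampler as [run_gibbs()], except that every `h`
#' iterations the response vector (together with its polygenic index, so the
#' y-to-pedigree linkage is preserved) is re-permuted against the genotype
#' rows.  The stored marker-effect draws sample the posterior of the marker
#' effects under the null of no genotype-phenotype association.
#'
#' @param y,genotypes,A As in [run_gibbs()].
#' @param control A [blasso_control()]; its `lambda` (fixed) is used for the
#'   permuted chain as for the observed chain.
#' @param perm A [perm_control()].
#' @return A `blasso_null` object (see [run_gibbs()]); the `beta_samples`
#'   matrix holds the null draws.
#' @export
run_permuted_chain <- function(y, genotypes, A = NULL,
                               control = blasso_control(),
                               perm = perm_control()) {
  stopifnot(inherits(control, "blasso_control"), inherits(perm, "perm_control"))
  if (perm$h > perm$niter) stop("h must not exceed the permuted-chain length")
  inp <- prepare_model_inputs(y, genotypes, A, control)
  sample_lambda <- is.null(control$lambda)
  lambda0 <- if (sample_lambda) sqrt(control$lambda_shape / control$lambda_rate)
             else control$lambda
  set.seed(perm$seed)
  raw <- .blasso_gibbs_cpp(inp$y, inp$X, inp$use_poly, inp$U, inp$d,
                           perm$niter, perm$burnin, perm$thin,
                           lambda0, sample_lambda,
                           control$lambda_shape, control$lambda_rate,
                           control$df_e, inp$scale_e,
                           !is.null(control$fix_sigma2e),
                           control$fix_sigma2e %||% 0,
                           control$df_s, inp$scale_s,
                           control$fix_mu, perm$h)
  finish_blasso_fit(raw, inp, control, permuted = TRUE, perm = perm)
}

#' Percentile critical values from null marker-effect draws
#'
#' Reads the `0.25 * alpha` and `1 - 0.25 * alpha` percentiles of the null
#' draws as lower and upper critical values, either per marker or from the
#' pooled draws of all markers.
#'
#' @param null A `blasso_null` object from [run_permuted_chain()], or a
#'   numeric matrix of null draws (markers in rows).
#' @param alpha Significance level.
#' @param scope `"per_marker"` or `"pooled"`.
#' @return Data frame (class `critical_values`) with columns `marker`,
#'   `lower`, `upper`; `alpha` and `scope` as attributes.
#' @export
critical_values <- function(null, alpha = 0.05,
                            scope = c("per_marker", "pooled")) {
  scope <- match.arg(scope)
  stopifnot(alpha > 0, alpha < 1)
  draws <- if (inherits(null, "blasso_fit")) null$beta_samples else as.matrix(null)
  if (length(draws) == 0 || ncol(draws) == 0) stop("empty null sample")
  if (scope == "per_marker" && ncol(draws) < 100)
    warning("fewer than 100 null draws per marker; per-marker percentiles ",
            "will be noisy")
  probs <- c(0.25 * alpha, 1 - 0.25 * alpha)
  if (scope == "pooled") {
    q <- stats::quantile(as.numeric(draws), probs, names = FALSE)
    lower <- rep(q[1], nrow(draws))
    upper <- rep(q[2], nrow(draws))
  } else {
    q <- apply(draws, 1, stats::quantile, probs = probs, names = FALSE)
    lower <- q[1, ]
    upper <- q[2, ]
  }
  out <- data.frame(marker = rownames(draws) %||% seq_len(nrow(draws)),
                    lower = lower, upper = upper)
  attr(out, "alpha") <- alpha
  attr(out, "scope") <- scope
  class(out) <- c("critical_values", class(out))
  out
}

#' Declare marker significance against permutation critical values
#'
#' A marker is significant when its posterior mean effect falls outside its
#' `[lower, upper]` critical interval.
#'
#' @param posterior A `blasso_fit` from [run_gibbs()], or a named numeric
#'   vector of posterior mean effects.
#' @param critical A [critical_values()] table over the same markers.
#' @return List of class `significance_result`: per-marker data frame
#'   (`marker`, `beta_mean`, `lower`, `upper`, `significant`), the number
#'   significant, and the fraction significant.
#' @export
declare_significant <- function(posterior, critical) {
  beta <- if (inherits(posterior, "blasso_fit")) posterior$beta_mean
          else posterior
  if (!identical(as.character(critical$marker), as.character(names(beta) %||% seq_along(beta))))
    stop("marker sets differ between posterior and critical values")
  sig <- beta < critical$lower | beta > critical$upper
  tab <- data.frame(marker = critical$marker, beta_mean = as.numeric(beta),
                    lower = critical$lower, upper = critical$upper,
                    significant = sig)
  structure(list(table = tab, n_significant = sum(sig),
                 fraction_significant = mean(sig),
                 alpha = attr(critical, "alpha"),
                 scope = attr(critical, "scope")),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat("significance at alpha =", x$alpha, "(", x$scope, "):",
      x$n_significant, "of", nrow(x$table), "markers",
      sprintf("(%.3f)\n", x$fraction_significant))
  invisible(x)
}

#' Select the markers with the largest absolute effects
#'
#' Markers sorted by absolute posterior mean effect, descending; ties are
#' broken by marker map order so the ranking is deterministic.
#'
#' @param posterior A `blasso_fit` or a named numeric vector of effects.
#' @param k Number of markers to return (`k >= p` returns all).
#' @param map Marker map; taken from the fit when omitted.
#' @return Data frame with columns `rank`, `marker`, `chrom`, `pos`,
#'   `beta_mean`, in decreasing `|beta_mean|` order.
#' @export
select_top_effects <- function(posterior, k = 100, map = NULL) {
  stopifnot(k >= 1)
  if (inherits(posterior, "blasso_fit")) {
    beta <- posterior$beta_mean
    map <- map %||% posterior$map
  } else {
    beta <- posterior
  }
  p <- length(beta)
  ord <- order(-abs(beta), seq_len(p))
  ord <- ord[seq_len(min(k, p))]
  out <- data.frame(rank = seq_along(ord),
                    marker = names(beta)[ord] %||% as.character(ord),
                    beta_mean = as.numeric(beta)[ord])
  if (!is.null(map)) {
    mi <- match(out$marker, map$marker)
    out$chrom <- map$chrom[mi]
    out$pos <- map$pos[mi]
    out <- out[, c("rank", "marker", "chrom", "pos", "beta_mean")]
  }
  out
}
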