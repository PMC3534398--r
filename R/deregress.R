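#' De-regress breeding values free of parent averages
#'
#' Produces de-regressed proofs (DRP) usable as pseudo-phenotypes in marker
#' regression.  For animals with parent information the two-equation
#' parent-average-removal system of Garrick, Taylor and Fernando is solved:
#' the information content (`Z'Z`) of the parent average and of the animal is
#' recovered from their reliabilities, the right-hand sides of the mixed
#' model equations are reconstructed from the EBVs, and the animal's own
#' right-hand side divided by its own information gives the proof with the
#' parent-average contribution removed.  For animals without parent
#' information the system reduces to the classical single-animal
#' de-regression `DRP = EBV / r2`.
#'
#' The record weight returned is `(1 - h2) / ((c + (1 - r2_drp) / r2_drp) *
#' h2)`, where `r2_drp` is the reliability of the de-regressed proof and `c`
#' is the fraction of genetic variance not explained by markers.
#'
#' @param ebv Animal EBV (vector).
#' @param reliability Animal EBV reliability r-squared, in (0, 1).
#' @param pa_ebv Parent-average EBV; `NA` for unknown parents.
#' @param pa_reliability Parent-average reliability; `NA` for unknown
#'   parents.
#' @param h2 Trait heritability.
#' @param c Fraction of genetic variance not captured by markers (default
#'   0.5).
#' @param clamp Reliabilities are clamped to this range to avoid division
#'   blow-ups.
#' @return Data frame with columns `drp`, `weight`, `reliability_drp`,
#'   `flagged` (`TRUE` when the animal carries essentially no information of
#'   its own beyond the parent average; such records should be excluded).
#' @export
deregress <- function(ebv, reliability, pa_ebv = NA_real_,
                      pa_reliability = NA_real_, h2, c = 0.5,
                      clamp = c(0.01, 0.99)) {
  n <- length(ebv)
  stopifnot(length(reliability) == n, h2 > 0, h2 < 1, c >= 0, c <= 1)
  pa_ebv <- rep_len(pa_ebv, n)
  pa_reliability <- rep_len(pa_reliability, n)
  r2 <- pmin(pmax(reliability, clamp[1]), clamp[2])
  lambda <- (1 - h2) / h2

  drp <- numeric(n)
  r2d <- numeric(n)
  flagged <- logical(n)
  has_pa <- !is.na(pa_ebv) & !is.na(pa_reliability)

  # founders / unknown parents: single-animal deregression
  i0 <- which(!has_pa)
  if (length(i0)) {
    drp[i0] <- ebv[i0] / r2[i0]
    r2d[i0] <- r2[i0]
  }

  i1 <- which(has_pa)
  if (length(i1)) {
    r2p <- pmin(pmax(pa_reliability[i1], clamp[1]), clamp[2])
    r2p <- pmin(r2p, 0.49)                    # a parent average cannot exceed 0.5
    r2i <- r2[i1]
    alpha <- 1 / (0.5 - r2p)
    delta <- (0.5 - r2p) / (1 - r2i)
    ZpZp <- lambda * (0.5 * alpha - 4) + 0.5 * lambda * sqrt(alpha^2 + 16 / delta)
    ZiZi <- delta * ZpZp + 2 * lambda * (2 * delta - 1)
    # MME right-hand side for the animal equation: -2*lambda*PA + (ZiZi + 2*lambda)*EBV
    rhs_i <- -2 * lambda * pa_ebv[i1] + (ZiZi + 2 * lambda) * ebv[i1]
    bad <- !is.finite(ZiZi) | ZiZi <= 0
    drp[i1] <- ifelse(bad, NA_real_, rhs_i / ZiZi)
    r2d[i1] <- ifelse(bad, NA_real_, ZiZi / (ZiZi + lambda))
    # essentially no own information: de-regressed reliability below ~5%
    flagged[i1] <- bad | r2i <= r2p | ZiZi <= 0.05 * lambda
  }

  if (any(flagged))
    warning(sum(flagged), " record(s) carry no own information beyond the ",
            "parent average and are flagged for exclusion")
  r2d_eff <- pmin(pmax(r2d, clamp[1]), clamp[2])
  weight <- (1 - h2) / ((c + (1 - r2d_eff) / r2d_eff) * h2)
  weight[is.na(drp)] <- NA_real_
  data.frame(drp = drp, weight = weight, reliability_drp = r2d,
             flagged = flagged)
}

#' De-regress a table of proxy records against a pedigree
#'
#' Computes each animal's parent-average EBV (mean of parental EBVs) and
#' parent-average reliability (`(r2_sire + r2_dam) / 4`) from the pedigree,
#' then applies [deregress()].  Animals with either parent unknown or
#' without a parental EBV are de-regressed as founders.
#'
#' @param proxies Data frame with columns `id`, `ebv`, `reliability` (e.g.
#'   from [simulate_ebv_proxies()]).
#' @param pedigree Data frame with columns `id`, `sire`, `dam`.
#' @param h2 Trait heritability.
#' @param ... Passed to [deregress()].
#' @return `proxies` with columns `drp`, `weight`, `reliability_drp`,
#'   `flagged` appended.
#' @export
deregress_records <- function(proxies, pedigree, h2, ...) {
  stopifnot(all(c("id", "ebv", "reliability") %in% names(proxies)))
  check_pedigree(pedigree)
  ped_idx <- match(proxies$id, pedigree$id)
  if (anyNA(ped_idx)) stop("all proxy records must appear in the pedigree")
  sire <- pedigree$sire[ped_idx]
  dam <- pedigree$dam[ped_idx]
  si <- match(sire, proxies$id)
  di <- match(dam, proxies$id)
  ok <- sire != 0 & dam != 0 & !is.na(si) & !is.na(di)
  pa_ebv <- ifelse(ok, (proxies$ebv[si] + proxies$ebv[di]) / 2, NA_real_)
  pa_rel <- ifelse(ok, (proxies$reliability[si] + proxies$reliability[di]) / 4,
                   NA_real_)
  out <- deregress(proxies$ebv, proxies$reliability, pa_ebv, pa_rel,
                   h2 = h2, ...)
  cbind(proxies, out)
}
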