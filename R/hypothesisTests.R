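#' Mann-Whitney U test with tie-corrected normal approximation
#'
#' Rank-sum test of whether two samples come from the same distribution.
#' Ranks are midranks (ties share the average rank); the reported
#' \code{U} is min(U1, U2) so U1 + U2 = n1*n2 always holds; \code{z} is
#' the signed normal deviate of U1 with the tie-corrected variance
#' n1*n2/12 * ((N+1) - sum(t^3 - t)/(N*(N-1))) and no continuity
#' correction; the two-sided p comes from the standard normal. When every
#' pooled value is identical the statistic is degenerate: z = 0, p = 1.
#'
#' @param x,y numeric vectors, each non-empty.
#' @return list of class \code{"mwuTest"}: \code{U}, \code{U1}, \code{U2},
#'   \code{z} (signed; x larger than y gives positive z), \code{p},
#'   \code{n1}, \code{n2}.
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))  # complete separation: U = 0
#' @export
mannWhitneyU <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  ties <- table(c(x, y))
  tieterm <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((N + 1) - tieterm / (N * (N - 1)))
  if (v <= 0) {
    out <- list(U = U1, U1 = U1, U2 = U2, z = 0, p = 1, n1 = n1, n2 = n2)
  } else {
    z <- (U1 - n1 * n2 / 2) / sqrt(v)
    out <- list(U = min(U1, U2), U1 = U1, U2 = U2, z = z,
                p = 2 * stats::pnorm(-abs(z)), n1 = n1, n2 = n2)
  }
  class(out) <- "mwuTest"
  out
}

#' @export
print.mwuTest <- function(x, ...) {
  cat("Mann-Whitney U test (tie-corrected normal approximation)\n")
  cat(sprintf("  n1 = %d, n2 = %d\n", x$n1, x$n2))
  cat(sprintf("  U = %g (U1 = %g, U2 = %g), z = %.4f, two-sided p = %.4g\n",
              x$U, x$U1, x$U2, x$z, x$p))
  invisible(x)
}

#' Monte-Carlo permutation test for a two-sample location difference
#'
#' Shuffles group labels over the pooled values (group sizes preserved) B
#' times and computes the two-sided p as (1 + number of permuted
#' |statistic| >= observed |statistic|) / (B + 1), the add-one estimator
#' that can never return 0. The default statistic is the difference in
#' medians; mean difference is also available. Degenerate pooled samples
#' (all values equal) give p = 1. Deterministic given \code{seed}.
#'
#' @param x,y numeric vectors.
#' @param statistic \code{"median"} or \code{"mean"} difference.
#' @param B number of label permutations (>= 99).
#' @param seed integer seed.
#' @return list: \code{p}, \code{observed} statistic, \code{B},
#'   \code{statistic}.
#' @export
monteCarloPermutation <- function(x, y, statistic = c("median", "mean"),
                                  B = 9999L, seed = 1L) {
  statistic <- match.arg(statistic)
  stopifnot(B >= 99)
  fn <- if (statistic == "median") stats::median else mean
  pool <- c(x, y); n1 <- length(x); N <- length(pool)
  obs <- abs(fn(x) - fn(y))
  if (length(unique(pool)) == 1L)
    return(list(p = 1, observed = 0, B = B, statistic = statistic))
  set.seed(childSeed(seed, 7L))
  hits <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(N, n1)
    if (abs(fn(pool[idx]) - fn(pool[-idx])) >= obs - 1e-12) hits <- hits + 1L
  }
  list(p = (1 + hits) / (B + 1), observed = obs, B = B, statistic = statistic)
}

#' Test observed regional Delta+ against a null ensemble
#'
#' Dataset A is the observed per-region Delta+ (one value per region where
#' it is defined); Dataset B pools the per-region Delta+ of every
#' randomized matrix in the ensemble (k values per defined region). Both
#' the tie-corrected Mann-Whitney U test and the Monte-Carlo permutation
#' test on the median difference are run; the verdict is
#' \code{"patterned"} (distribution deviates from random assembly) only if
#' both p-values fall below \code{alpha}, else \code{"random"}. With
#' \code{pooled = FALSE} the U test is additionally run against each
#' replicate separately, mirroring a repeated observed-vs-single-null
#' design.
#'
#' @param results data.frame from [groupDeltaTable()] (flags need not be
#'   filled; regions with richness < 2 are excluded from both sides).
#' @param ensemble a [NullEnsemble-class].
#' @param B permutation count for the Monte-Carlo test.
#' @param seed integer seed.
#' @param alpha significance level (default 0.05, two-sided).
#' @param pooled also report per-replicate U tests when FALSE.
#' @return list of class \code{"tdTest"}: \code{mwu} (the U test),
#'   \code{permutation}, \code{verdict}, \code{alpha}, \code{nObs},
#'   \code{nNull}, and \code{perReplicate} (NULL unless requested).
#' @export
observedVsNullTest <- function(results, ensemble, B = 9999L, seed = 1L,
                               alpha = 0.05, pooled = TRUE) {
  obs <- results[results$richness >= 2 & !is.na(results$deltaPlus), ]
  if (nrow(obs) < 2L) stop("fewer than 2 regions with defined Delta+")
  nul <- nullDeltaTable(ensemble)
  nul <- nul[nul$region %in% obs$region, ]
  x <- obs$deltaPlus
  y <- nul$deltaPlus
  mwu <- mannWhitneyU(x, y)
  perm <- monteCarloPermutation(x, y, "median", B = B, seed = seed)
  verdict <- if (mwu$p < alpha && perm$p < alpha) "patterned" else "random"
  perRep <- NULL
  if (!pooled) {
    perRep <- lapply(split(nul, nul$replicate), function(d)
      mannWhitneyU(x, d$deltaPlus))
  }
  out <- list(mwu = mwu, permutation = perm, verdict = verdict,
              alpha = alpha, nObs = length(x), nNull = length(y),
              perReplicate = perRep)
  class(out) <- "tdTest"
  out
}

#' @export
print.tdTest <- function(x, ...) {
  cat("Observed vs. null taxonomic distinctness\n")
  cat(sprintf("  %d observed regions vs %d pooled null values\n",
              x$nObs, x$nNull))
  cat(sprintf("  U = %g, z = %.4f, asymptotic p = %.4g\n",
              x$mwu$U, x$mwu$z, x$mwu$p))
  cat(sprintf("  permutation p = %.4g (B = %d, %s difference)\n",
              x$permutation$p, x$permutation$B, x$permutation$statistic))
  cat("  verdict:", x$verdict, "at alpha =", x$alpha, "\n")
  invisible(x)
}
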