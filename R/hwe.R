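#' Exact test of Hardy-Weinberg equilibrium
#'
#' Multi-allelic exact test conditioning on the observed allele counts,
#' with the conventional probability ordering: the p-value is the total
#' probability of genotype tables no more probable than the observed one.
#' Small problems (at most 3 alleles and 50 individuals) are solved by
#' complete enumeration of all tables; larger ones by a Metropolis chain
#' over tables with switch proposals (the Markov-chain approach of the
#' classic multi-allelic exact test), whose Monte Carlo standard error is
#' estimated by batch means. Monte Carlo p-values use the
#' \eqn{(b+1)/(m+1)} convention and so never return 0.
#'
#' @param genos two-column matrix of allele labels (diploid genotypes).
#' @param dememorization burn-in steps for the chain.
#' @param steps recorded chain steps.
#' @param seed integer seed (Monte Carlo path only).
#' @param method `"auto"` (enumerate when feasible), `"enumeration"` or
#'   `"mcmc"`.
#' @return object of class `hwe_test`: list with `p_value`, `se` (Monte
#'   Carlo standard error; 0 for enumeration), `method`, `note`, `n`,
#'   `n_alleles`, `seed`, `steps`.
#' @export
hwe_exact <- function(genos, dememorization = 1e5, steps = 1e6,
                      seed = 1L, method = c("auto", "enumeration", "mcmc")) {
  method <- match.arg(method)
  g <- as_geno_matrix(genos)
  n <- nrow(g)
  labs <- sort_alleles(unique(c(g[, 1], g[, 2])))
  k <- length(labs)
  res <- list(n = n, n_alleles = k, seed = as.integer(seed),
              steps = NA_real_, se = 0, note = NULL)
  if (k < 2) {
    res$p_value <- 1
    res$method <- "none"
    res$note <- "monomorphic locus"
    class(res) <- "hwe_test"
    return(res)
  }
  if (n < 5) stop("need at least 5 diploid genotypes", call. = FALSE)
  a <- match(g[, 1], labs)
  b <- match(g[, 2], labs)
  if (method == "auto") {
    method <- if (k <= 3 && n <= 50) "enumeration" else "mcmc"
  }
  if (method == "enumeration") {
    if (k > 3) stop("complete enumeration supports at most 3 alleles",
                    call. = FALSE)
    res$p_value <- hwe_enumerate_p(a, b, k)
    res$method <- "enumeration"
  } else {
    out <- with_seed(seed, .hwe_chain(a - 1L, b - 1L, k,
                                      as.integer(dememorization),
                                      as.integer(steps)))
    res$p_value <- out$p_value
    res$se <- out$se
    res$steps <- out$steps
    res$method <- "mcmc"
  }
  class(res) <- "hwe_test"
  res
}

#' @export
print.hwe_test <- function(x, ...) {
  cat(sprintf("HWE exact test (%s): p = %.6g", x$method, x$p_value))
  if (x$method == "mcmc") cat(sprintf(" (MC se %.2g, %g steps)", x$se,
                                      x$steps))
  if (!is.null(x$note)) cat(" [", x$note, "]", sep = "")
  cat("\n")
  invisible(x)
}

# log of the variable part of the conditional table probability:
# H log 2 - sum lgamma(n_ij + 1)
table_log_prob <- function(het, cells) {
  het * log(2) - sum(lgamma(cells + 1))
}

# Complete enumeration for k <= 3 alleles. a, b: integer allele codes.
hwe_enumerate_p <- function(a, b, k) {
  m <- tabulate(c(a, b), nbins = k)  # allele copy counts
  n <- length(a)
  # observed table
  obs_cells <- table(factor(pmin(a, b), levels = 1:k),
                     factor(pmax(a, b), levels = 1:k))
  obs_log <- table_log_prob(sum(a != b), obs_cells[upper.tri(obs_cells,
                                                             diag = TRUE)])
  logs <- c()
  if (k == 2) {
    for (n12 in seq(m[1] %% 2, min(m[1], m[2]), by = 2)) {
      n11 <- (m[1] - n12) / 2
      n22 <- (m[2] - n12) / 2
      logs <- c(logs, table_log_prob(n12, c(n11, n12, n22)))
    }
  } else {
    for (n12 in 0:min(m[1], m[2])) for (n13 in 0:min(m[1] - n12, m[3])) {
      if ((m[1] - n12 - n13) %% 2 != 0) next
      n11 <- (m[1] - n12 - n13) / 2
      for (n23 in 0:min(m[2] - n12, m[3] - n13)) {
        if ((m[2] - n12 - n23) %% 2 != 0) next
        if ((m[3] - n13 - n23) %% 2 != 0) next
        n22 <- (m[2] - n12 - n23) / 2
        n33 <- (m[3] - n13 - n23) / 2
        logs <- c(logs, table_log_prob(
          n12 + n13 + n23, c(n11, n12, n13, n22, n23, n33)))
      }
    }
  }
  w <- exp(logs - max(logs))
  sum(w[logs <= obs_log + 1e-9]) / sum(w)
}

#' Bonferroni-corrected significance threshold
#'
#' The per-test threshold for family-wise level `alpha` over `m` tests is
#' `alpha / m`; reports round it to 4 decimals alongside full precision.
#'
#' @param alpha family-wise significance level.
#' @param m number of tests (>= 1).
#' @return the per-test threshold `alpha / m` at full precision, with the
#'   4-decimal value as attribute `"rounded"`.
#' @examples
#' bonferroni(0.05, 19)  # 0.002631..., printed as 0.0026
#' @export
bonferroni <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  structure(alpha / m, rounded = round(alpha / m, 4))
}
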