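#' Two-locus haplotype frequencies from male X data
#'
#' Males are hemizygous, so their X haplotypes are read directly: one
#' allele per locus per male. Haplotypes are labelled
#' `"<allele1>-<allele2>"`.
#'
#' @param x a [genotype_table()].
#' @param loci character vector of two X locus names.
#' @return data.frame with columns `haplotype`, `count`, `frequency`
#'   (frequencies sum to 1), ordered by decreasing count.
#' @export
haplotype_frequencies <- function(x, loci) {
  stopifnot(inherits(x, "genotype_table"), length(loci) == 2)
  if (any(panel_class(x$panel, loci) != "X")) {
    stop("haplotype counting needs two X loci", call. = FALSE)
  }
  c1 <- locus_calls(x, loci[1], "M")
  c2 <- locus_calls(x, loci[2], "M")
  ids <- intersect(c1$sample_id, c2$sample_id)
  if (length(ids) == 0) stop("no males typed at both loci", call. = FALSE)
  h <- paste(c1$a1[match(ids, c1$sample_id)],
             c2$a1[match(ids, c2$sample_id)], sep = "-")
  cnt <- sort(table(h), decreasing = TRUE)
  data.frame(haplotype = names(cnt), count = as.integer(cnt),
             frequency = as.integer(cnt) / length(ids),
             stringsAsFactors = FALSE, row.names = NULL)
}

# G (likelihood-ratio) statistic of independence on a contingency table
# given two integer code vectors.
g_statistic <- function(i1, i2, k1, k2) {
  o <- tabulate(i1 + k1 * (i2 - 1L), nbins = k1 * k2)
  n <- length(i1)
  r <- tabulate(i1, nbins = k1)
  c2 <- tabulate(i2, nbins = k2)
  e <- outer(r, c2) / n
  o <- matrix(o, k1, k2)
  keep <- o > 0
  2 * sum(o[keep] * log(o[keep] / e[keep]))
}

# EM haplotype-frequency estimation for two loci from unphased diploid
# genotypes. g1, g2: n x 2 integer allele-code matrices. Returns the
# k1 x k2 haplotype frequency matrix and the maximized log-likelihood.
em_haplotypes <- function(g1, g2, k1, k2, max_iter = 500, tol = 1e-10) {
  n <- nrow(g1)
  # start from the product of marginal allele frequencies
  p1 <- tabulate(c(g1), nbins = k1) / (2 * n)
  p2 <- tabulate(c(g2), nbins = k2) / (2 * n)
  h <- outer(p1, p2)
  dh1 <- g1[, 1] != g1[, 2]
  dh2 <- g2[, 1] != g2[, 2]
  amb <- dh1 & dh2  # double heterozygotes: two possible phases
  for (it in seq_len(max_iter)) {
    # phase 1: (a1,c1)+(a2,c2); phase 2: (a1,c2)+(a2,c1)
    w1 <- h[cbind(g1[, 1], g2[, 1])] * h[cbind(g1[, 2], g2[, 2])]
    w2 <- h[cbind(g1[, 1], g2[, 2])] * h[cbind(g1[, 2], g2[, 1])]
    pr1 <- ifelse(amb, ifelse(w1 + w2 > 0, w1 / (w1 + w2), 0.5), 1)
    pr2 <- ifelse(amb, 1 - pr1, 0)
    lin <- c(g1[, 1] + k1 * (g2[, 1] - 1L), g1[, 2] + k1 * (g2[, 2] - 1L),
             g1[, 1] + k1 * (g2[, 2] - 1L), g1[, 2] + k1 * (g2[, 1] - 1L))
    w <- c(pr1, pr1, pr2, pr2)
    acc <- rowsum(w, lin)
    cnt <- numeric(k1 * k2)
    cnt[as.integer(rownames(acc))] <- acc
    hn <- matrix(cnt, k1, k2) / (2 * n)
    if (max(abs(hn - h)) < tol) {
      h <- hn
      break
    }
    h <- hn
  }
  w1 <- h[cbind(g1[, 1], g2[, 1])] * h[cbind(g1[, 2], g2[, 2])]
  w2 <- h[cbind(g1[, 1], g2[, 2])] * h[cbind(g1[, 2], g2[, 1])]
  mult1 <- ifelse(g1[, 1] == g1[, 2] & g2[, 1] == g2[, 2], 1, 2)
  lik <- ifelse(amb, 2 * w1 + 2 * w2, mult1 * w1)
  list(h = h, loglik = sum(log(pmax(lik, 1e-300))))
}

em_lr_statistic <- function(g1, g2, k1, k2, max_iter = 500, tol = 1e-10) {
  n <- nrow(g1)
  p1 <- tabulate(c(g1), nbins = k1) / (2 * n)
  p2 <- tabulate(c(g2), nbins = k2) / (2 * n)
  h0 <- outer(p1, p2)
  fit <- em_haplotypes(g1, g2, k1, k2, max_iter = max_iter, tol = tol)
  # log-likelihood under independence: same expression with h = p1 x p2
  w1 <- h0[cbind(g1[, 1], g2[, 1])] * h0[cbind(g1[, 2], g2[, 2])]
  w2 <- h0[cbind(g1[, 1], g2[, 2])] * h0[cbind(g1[, 2], g2[, 1])]
  amb <- (g1[, 1] != g1[, 2]) & (g2[, 1] != g2[, 2])
  mult1 <- ifelse(g1[, 1] == g1[, 2] & g2[, 1] == g2[, 2], 1, 2)
  lik0 <- ifelse(amb, 2 * w1 + 2 * w2, mult1 * w1)
  l0 <- sum(log(pmax(lik0, 1e-300)))
  list(stat = 2 * (fit$loglik - l0), h = fit$h)
}

#' Permutation test of two-locus linkage disequilibrium
#'
#' Two data situations:
#' \describe{
#'   \item{males (phase known)}{hemizygous X haplotypes; the G
#'     (likelihood-ratio) statistic of the two-locus haplotype contingency
#'     table, with a permutation null obtained by shuffling one locus's
#'     alleles across individuals.}
#'   \item{females (phase unknown)}{diploid genotypes; haplotype
#'     frequencies under linkage are estimated by EM and compared with the
#'     independence model by a likelihood-ratio statistic, permuting one
#'     locus's genotypes for the null.}
#' }
#' Permutation p-values use the \eqn{(b+1)/(m+1)} convention.
#'
#' @param x a [genotype_table()].
#' @param loci character vector of two locus names.
#' @param sex `"M"` (haplotypic, X males) or `"F"` (genotypic, diploid).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return object of class `ld_test`: list with `statistic`, `p_value`,
#'   `n_perm`, `n`, `sex`, `seed`, and for females the EM haplotype
#'   frequency matrix `haplotypes`.
#' @export
ld_test <- function(x, loci, sex = c("F", "M"), n_perm = 10000, seed = 1L) {
  sex <- match.arg(sex)
  stopifnot(inherits(x, "genotype_table"), length(loci) == 2)
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  c1 <- locus_calls(x, loci[1], sex)
  c2 <- locus_calls(x, loci[2], sex)
  ids <- intersect(c1$sample_id, c2$sample_id)
  if (length(ids) < 5) stop("too few individuals typed at both loci",
                            call. = FALSE)
  c1 <- c1[match(ids, c1$sample_id), ]
  c2 <- c2[match(ids, c2$sample_id), ]
  out <- list(loci = loci, sex = sex, n = length(ids),
              n_perm = as.integer(n_perm), seed = as.integer(seed))
  if (sex == "M") {
    if (any(panel_class(x$panel, loci) != "X") ||
        !all(is.na(c1$a2)) || !all(is.na(c2$a2))) {
      stop("male haplotypic LD needs hemizygous X calls at both loci",
           call. = FALSE)
    }
    l1 <- sort_alleles(unique(c1$a1)); l2 <- sort_alleles(unique(c2$a1))
    i1 <- match(c1$a1, l1); i2 <- match(c2$a1, l2)
    k1 <- length(l1); k2 <- length(l2)
    obs <- g_statistic(i1, i2, k1, k2)
    perm <- with_seed(seed, vapply(seq_len(n_perm), function(r) {
      g_statistic(i1, sample(i2), k1, k2)
    }, numeric(1)))
  } else {
    if (anyNA(c1$a2) || anyNA(c2$a2)) {
      stop("female genotypic LD needs diploid calls at both loci",
           call. = FALSE)
    }
    l1 <- sort_alleles(unique(c(c1$a1, c1$a2)))
    l2 <- sort_alleles(unique(c(c2$a1, c2$a2)))
    k1 <- length(l1); k2 <- length(l2)
    g1 <- cbind(match(c1$a1, l1), match(c1$a2, l1))
    g2 <- cbind(match(c2$a1, l2), match(c2$a2, l2))
    # bounded EM (same settings for the observed and permuted statistics):
    # the LR statistic stabilizes within a few dozen iterations and the
    # permutation ranking is insensitive to the tail of the EM path
    fit <- em_lr_statistic(g1, g2, k1, k2, max_iter = 60, tol = 1e-6)
    obs <- fit$stat
    dimnames(fit$h) <- list(l1, l2)
    out$haplotypes <- fit$h
    perm <- with_seed(seed, vapply(seq_len(n_perm), function(r) {
      idx <- sample(nrow(g2))
      em_lr_statistic(g1, g2[idx, , drop = FALSE], k1, k2,
                      max_iter = 60, tol = 1e-6)$stat
    }, numeric(1)))
  }
  out$statistic <- obs
  out$p_value <- (sum(perm >= obs - 1e-12) + 1) / (n_perm + 1)
  class(out) <- "ld_test"
  out
}

#' @export
print.ld_test <- function(x, ...) {
  cat(sprintf(
    "LD permutation test %s x %s (%s, n=%d): stat = %.4f, p = %.6g (%d perms)\n",
    x$loci[1], x$loci[2], if (x$sex == "M") "male haplotypic"
    else "female genotypic", x$n, x$statistic, x$p_value, x$n_perm))
  invisible(x)
}
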