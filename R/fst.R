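#' Pairwise Weir-Cockerham F_ST with permutation p-values
#'
#' Estimates theta (Weir & Cockerham 1984) for every pair of populations,
#' combining loci and alleles by the ratio of summed variance components.
#' Autosomal loci use the diploid a/b/c components (which account for
#' observed heterozygosity); X loci are treated as haploid allele-copy
#' samples — one copy per male, two per female — with the corresponding
#' one-way ANOVA components. Negative estimates are retained. Significance
#' is assessed by permuting individuals between the two populations and
#' recomputing theta; p-values use the \eqn{(b+1)/(m+1)} convention.
#'
#' @param x a [genotype_table()] containing two or more populations.
#' @param loci loci to include (default: whole panel).
#' @param n_perm permutations per pair (0 skips p-values).
#' @param seed integer seed.
#' @return object of class `fst_matrix`: list with `populations`, `fst`
#'   (symmetric matrix, zero diagonal), `p_value` (matrix or `NULL`),
#'   `n_perm`.
#' @export
pairwise_fst <- function(x, loci = NULL, n_perm = 10000, seed = 1L) {
  stopifnot(inherits(x, "genotype_table"))
  if (is.null(loci)) loci <- x$panel$locus
  pops <- unique(x$samples$population)
  if (length(pops) < 2) stop("need >= 2 populations", call. = FALSE)
  sizes <- table(x$samples$population)
  if (any(sizes < 2)) {
    stop("every population needs >= 2 individuals", call. = FALSE)
  }
  prep <- fst_prepare(x, loci)
  npop <- length(pops)
  fst <- matrix(0, npop, npop, dimnames = list(pops, pops))
  pmat <- if (n_perm > 0) fst + NA else NULL
  if (!is.null(pmat)) diag(pmat) <- NA
  for (i in seq_len(npop - 1)) for (j in (i + 1):npop) {
    assign0 <- ifelse(x$samples$population == pops[i], 1L,
                      ifelse(x$samples$population == pops[j], 2L, NA))
    keep <- !is.na(assign0)
    obs <- fst_theta(prep, assign0)
    fst[i, j] <- fst[j, i] <- obs
    if (n_perm > 0) {
      hits <- with_seed(derive_seed(seed, paste(pops[i], pops[j])), {
        sum(vapply(seq_len(n_perm), function(r) {
          perm <- assign0
          perm[keep] <- sample(assign0[keep])
          fst_theta(prep, perm) >= obs - 1e-12
        }, logical(1)))
      })
      pmat[i, j] <- pmat[j, i] <- (hits + 1) / (n_perm + 1)
    }
  }
  structure(list(populations = pops, fst = fst, p_value = pmat,
                 n_perm = as.integer(n_perm)),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("pairwise Weir-Cockerham F_ST\n")
  print(round(x$fst, 5))
  if (!is.null(x$p_value)) {
    cat(sprintf("permutation p-values (%d permutations)\n", x$n_perm))
    print(round(x$p_value, 5))
  }
  invisible(x)
}

# Precompute, per locus, the per-individual allele-count matrix used by
# the theta computation: rows indexed into x$samples, columns alleles.
fst_prepare <- function(x, loci) {
  chrom <- panel_class(x$panel, loci)
  lapply(seq_along(loci), function(i) {
    lc <- loci[i]
    cl <- locus_calls(x, lc)
    labs <- sort_alleles(unique(c(cl$a1, cl$a2[!is.na(cl$a2)])))
    k <- length(labs)
    C <- matrix(0L, nrow(cl), k)
    C[cbind(seq_len(nrow(cl)), match(cl$a1, labs))] <-
      C[cbind(seq_len(nrow(cl)), match(cl$a1, labs))] + 1L
    dip <- !is.na(cl$a2)
    C[cbind(which(dip), match(cl$a2[dip], labs))] <-
      C[cbind(which(dip), match(cl$a2[dip], labs))] + 1L
    list(
      sample_idx = match(cl$sample_id, x$samples$sample_id),
      C = C,
      het = (C == 1L) * (rowSums(C) == 2L),  # heterozygote indicators
      ploidy = rowSums(C),
      diploid = chrom[i] == "autosomal"
    )
  })
}

# Multi-locus theta for a 1/2/NA population assignment over x$samples.
fst_theta <- function(prep, assign) {
  num <- 0; den <- 0
  for (loc in prep) {
    pop <- assign[loc$sample_idx]
    keep <- !is.na(pop)
    if (!any(keep)) next
    pop <- pop[keep]
    if (length(unique(pop)) < 2) next
    C <- loc$C[keep, , drop = FALSE]
    if (loc$diploid) {
      cnt_i <- rowsum(C, pop)                    # allele copies per pop
      het_i <- rowsum(loc$het[keep, , drop = FALSE], pop)
      n_i <- tabulate(pop, 2)                    # individuals per pop
      if (any(n_i < 2)) next
      r <- 2
      nbar <- mean(n_i)
      nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
      p_i <- cnt_i / (2 * n_i)
      h_i <- het_i / n_i
      pbar <- colSums(n_i * p_i) / sum(n_i)
      s2 <- colSums(n_i * (p_i - rep(pbar, each = r))^2) / ((r - 1) * nbar)
      hbar <- colSums(n_i * h_i) / sum(n_i)
      a <- nbar / nc *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + sum(a)
      den <- den + sum(a + b + cc)
    } else {
      # haploid components on allele copies (males 1, females 2)
      cnt_i <- rowsum(C, pop)
      n_i <- rowsum(loc$ploidy[keep], pop)[, 1]  # copies per pop
      if (any(n_i < 2)) next
      r <- 2
      N <- sum(n_i)
      p_i <- cnt_i / n_i
      pbar <- colSums(n_i * p_i) / N
      msp <- colSums(n_i * (p_i - rep(pbar, each = r))^2) / (r - 1)
      msg <- colSums(n_i * p_i * (1 - p_i)) / (N - r)
      nc <- (N - sum(n_i^2) / N) / (r - 1)
      a <- (msp - msg) / nc
      num <- num + sum(a)
      den <- den + sum(a + msg)
    }
  }
  if (den == 0) return(0)
  num / den
}

#' Hierarchically ordered distance matrix
#'
#' Reorders a symmetric distance matrix by average-linkage hierarchical
#' clustering, the ordering used for distance heatmaps; writing the result
#' to TSV is the package's heatmap export (no graphics dependency).
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param path optional TSV output path.
#' @return the reordered matrix (invisibly if `path` is given).
#' @export
ordered_distance_matrix <- function(d, path = NULL) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric",
                                    call. = FALSE)
  # average-linkage ordering; clustering tolerates slightly negative
  # distances by shifting to zero
  ord <- stats::hclust(stats::as.dist(pmax(d, 0)), method = "average")$order
  out <- d[ord, ord]
  if (!is.null(path)) {
    utils::write.table(
      data.frame(population = rownames(out), out, check.names = FALSE),
      path, sep = "\t", quote = FALSE, row.names = FALSE,
      fileEncoding = "UTF-8")
    return(invisible(out))
  }
  out
}
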