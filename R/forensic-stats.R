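#' Allele-frequency power sums
#'
#' \eqn{a_k = \sum_i p_i^k}. Most forensic parameters are polynomials in
#' these sums.
#'
#' @param p numeric frequency vector (sums to 1).
#' @param k exponents.
#' @return named numeric vector `a2`, `a3`, ...
#' @export
power_sums <- function(p, k = 2:5) {
  stats::setNames(vapply(k, function(kk) sum(p^kk), numeric(1)),
                  paste0("a", k))
}

check_freqs <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
    stop("frequencies must be non-negative and sum to 1", call. = FALSE)
  }
  invisible(p)
}

# genos: 2-column matrix/data.frame of allele labels, diploid rows only
as_geno_matrix <- function(genos) {
  g <- as.matrix(genos)
  if (ncol(g) != 2) stop("genotypes must have two allele columns",
                         call. = FALSE)
  if (anyNA(g)) stop("diploid genotypes must not contain NA alleles",
                     call. = FALSE)
  g
}

#' Observed and unbiased expected heterozygosity
#'
#' \eqn{H_o} is the fraction of heterozygous genotypes. \eqn{H_e} uses the
#' small-sample correction on the number of sampled allele copies \eqn{n}:
#' \eqn{H_e = \frac{n}{n-1}(1 - \sum_i p_i^2)}.
#'
#' @param genos two-column matrix of allele labels (one row per diploid
#'   individual).
#' @return named vector `c(Ho, He)`.
#' @export
heterozygosities <- function(genos) {
  g <- as_geno_matrix(genos)
  if (nrow(g) < 2) stop("need at least 2 diploid individuals", call. = FALSE)
  ho <- mean(g[, 1] != g[, 2])
  p <- as.numeric(table(c(g[, 1], g[, 2])))
  p <- p / sum(p)
  n <- 2 * nrow(g)
  he <- n / (n - 1) * (1 - sum(p^2))
  c(Ho = ho, He = he)
}

#' Polymorphism information content
#'
#' \eqn{PIC = 1 - a_2 - a_2^2 + a_4}.
#'
#' @param p frequency vector summing to 1.
#' @return PIC in \[0, 1\].
#' @export
pic <- function(p) {
  check_freqs(p)
  a <- power_sums(p, c(2, 4))
  unname(1 - a["a2"] - a["a2"]^2 + a["a4"])
}

#' Match probability and power of discrimination
#'
#' Observed mode sums squared genotype proportions over the sample;
#' expected mode sums squared Hardy-Weinberg genotype probabilities from a
#' frequency vector. \eqn{PD = 1 - MP} always.
#'
#' @param genos two-column matrix of allele labels (observed mode).
#' @param p frequency vector (expected mode).
#' @param mode `"observed"` or `"expected"`.
#' @return named vector `c(MP, PD)`.
#' @export
match_probability <- function(genos = NULL, p = NULL,
                              mode = c("observed", "expected")) {
  mode <- match.arg(mode)
  if (mode == "observed") {
    g <- as_geno_matrix(genos)
    key <- paste(pmin(g[, 1], g[, 2]), pmax(g[, 1], g[, 2]), sep = "/")
    gp <- as.numeric(table(key)) / nrow(g)
  } else {
    check_freqs(p)
    gp <- hwe_genotype_probs(p)$prob
  }
  mp <- sum(gp^2)
  c(MP = mp, PD = 1 - mp)
}

# All unordered genotypes {i, j} with HWE probabilities for freq vector p.
hwe_genotype_probs <- function(p) {
  k <- length(p)
  i <- rep(seq_len(k), times = k)
  j <- rep(seq_len(k), each = k)
  keep <- i <= j
  i <- i[keep]; j <- j[keep]
  prob <- ifelse(i == j, p[i]^2, 2 * p[i] * p[j])
  data.frame(i = i, j = j, prob = prob)
}

#' Power of exclusion and typical paternity index
#'
#' With \eqn{h} the observed heterozygote proportion and \eqn{H = 1 - h}:
#' \eqn{PE = h^2 (1 - 2 h H^2)} and \eqn{TPI = 1 / (2H)}. At \eqn{H = 0}
#' (every genotype heterozygous) TPI is reported as `Inf` with a warning.
#'
#' @param genos two-column matrix of allele labels.
#' @return named vector `c(PE, TPI)`.
#' @export
exclusion_and_tpi <- function(genos) {
  g <- as_geno_matrix(genos)
  h <- mean(g[, 1] != g[, 2])
  H <- 1 - h
  pe <- h^2 * (1 - 2 * h * H^2)
  if (H == 0) {
    warning("no homozygotes observed; TPI is infinite", call. = FALSE)
    tpi <- Inf
  } else {
    tpi <- 1 / (2 * H)
  }
  c(PE = pe, TPI = tpi)
}

#' X-chromosomal discrimination parameters
#'
#' Hemizygous males expose single alleles, so the male power of
#' discrimination is \eqn{PD_m = 1 - a_2}; females are diploid and
#' \eqn{PD_f = 1 - 2 a_2^2 + a_4} (identically \eqn{1 - \sum g^2} over
#' Hardy-Weinberg genotype probabilities). Gene diversity \eqn{HD} applies
#' the \eqn{n/(n-1)} correction for `n` sampled allele copies.
#'
#' @param p frequency vector summing to 1.
#' @param n number of allele copies behind `p` (for HD); `NULL` omits the
#'   correction.
#' @return named vector `c(PD_male, PD_female, HD)`.
#' @export
x_discrimination <- function(p, n = NULL) {
  check_freqs(p)
  a <- power_sums(p, c(2, 4))
  pdm <- 1 - a[["a2"]]
  pdf_ <- 1 - 2 * a[["a2"]]^2 + a[["a4"]]
  hd <- if (is.null(n)) 1 - a[["a2"]] else n / (n - 1) * (1 - a[["a2"]])
  c(PD_male = pdm, PD_female = pdf_, HD = hd)
}

#' Combine per-locus forensic parameters across a panel
#'
#' Independent loci multiply: the combined match probability is the product
#' of per-locus MP (`CPM`), the combined discrimination power its
#' complement (`CPD = 1 - CPM`), and the combined exclusion power is one
#' minus the product of per-locus exclusion complements
#' (`CPE = 1 - prod(1 - PE)`). The same product-of-complements rule yields
#' combined X metrics.
#'
#' @param mp per-locus match probabilities (optional).
#' @param pe per-locus exclusion powers (optional).
#' @return list with `CPM`, `CPD`, `CPE` (those whose inputs were given).
#' @export
combine_forensic <- function(mp = NULL, pe = NULL) {
  out <- list()
  if (!is.null(mp)) {
    if (length(mp) < 1) stop("need >= 1 locus", call. = FALSE)
    out$CPM <- prod(mp)
    out$CPD <- 1 - out$CPM
  }
  if (!is.null(pe)) {
    if (length(pe) < 1) stop("need >= 1 locus", call. = FALSE)
    out$CPE <- 1 - prod(1 - pe)
  }
  out
}

#' Per-locus forensic parameter table
#'
#' For autosomal loci (and, in females, X loci) computes Ho, unbiased He,
#' PIC, observed-mode MP/PD, PE and TPI; for X loci additionally the male
#' and female discrimination powers and gene diversity from pooled
#' frequencies. Combined values (CPM/CPD/CPE over autosomal loci; combined
#' PD_m/PD_f and MEC over X loci) are attached as attribute `"combined"`.
#'
#' @param x a [genotype_table()].
#' @param loci loci to include (default: whole panel).
#' @return data.frame, one row per locus, with attribute `"combined"`.
#' @export
forensic_summary <- function(x, loci = NULL) {
  stopifnot(inherits(x, "genotype_table"))
  if (is.null(loci)) loci <- x$panel$locus
  chrom <- panel_class(x$panel, loci)
  rows <- vector("list", length(loci))
  for (i in seq_along(loci)) {
    lc <- loci[i]
    xlink <- chrom[i] == "X"
    dip <- locus_calls(x, lc, if (xlink) "F" else "both")
    dip <- dip[!is.na(dip$a2), , drop = FALSE]
    g <- as.matrix(dip[c("a1", "a2")])
    het <- if (nrow(g) >= 2) heterozygosities(g) else c(Ho = NA, He = NA)
    mpd <- if (nrow(g) >= 1) match_probability(g, mode = "observed") else
      c(MP = NA, PD = NA)
    pet <- if (nrow(g) >= 1) suppressWarnings(exclusion_and_tpi(g)) else
      c(PE = NA, TPI = NA)
    row <- data.frame(
      locus = lc, chromosome = chrom[i], n_diploid = nrow(g),
      Ho = het[["Ho"]], He = het[["He"]],
      MP = mpd[["MP"]], PD = mpd[["PD"]],
      PE = pet[["PE"]], TPI = pet[["TPI"]],
      stringsAsFactors = FALSE)
    ft <- frequencies_from_table(x, "pooled", lc)
    p <- freq_vector(ft, lc)
    row$PIC <- pic(p)
    if (xlink) {
      xd <- x_discrimination(p, n = locus_sample_size(ft, lc))
      row$PD_male <- xd[["PD_male"]]
      row$PD_female <- xd[["PD_female"]]
      row$HD <- xd[["HD"]]
      row$MEC_x_trio <- mec(p, "X_TRIO_DAUGHTER")
      row$MEC_x_duo <- mec(p, "X_DUO_FATHER_DAUGHTER")
    } else {
      row$PD_male <- row$PD_female <- row$HD <- NA_real_
      row$MEC_x_trio <- row$MEC_x_duo <- NA_real_
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  auto <- out[out$chromosome == "autosomal" & !is.na(out$MP), ]
  xl <- out[out$chromosome == "X", ]
  combined <- list()
  if (nrow(auto) > 0) {
    combined <- combine_forensic(mp = auto$MP, pe = auto$PE)
  }
  if (nrow(xl) > 0) {
    combined$CPD_male <- 1 - prod(1 - xl$PD_male)
    combined$CPD_female <- 1 - prod(1 - xl$PD_female)
    combined$CMEC_x_trio <- 1 - prod(1 - xl$MEC_x_trio)
    combined$CMEC_x_duo <- 1 - prod(1 - xl$MEC_x_duo)
  }
  attr(out, "combined") <- combined
  out
}
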