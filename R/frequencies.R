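#' Construct an allele-frequency table
#'
#' The reference-database object: per locus, a map from allele label to
#' relative frequency plus the number of allele copies sampled. This is the
#' object that supplies \eqn{p_A} and \eqn{p_B} to the match-probability
#' formulas.
#'
#' @param df data.frame with columns `locus`, `allele`, `frequency`, `n`
#'   (allele copies sampled at that locus).
#' @param population optional source-population label, stored as an
#'   attribute.
#' @return data.frame of class `allele_freq_table`.
#' @export
allele_freq_table <- function(df, population = NA_character_) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("locus", "allele", "frequency", "n")
  if (!all(need %in% names(df))) {
    stop("needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  df$locus <- as.character(df$locus)
  df$allele <- as.character(df$allele)
  df$frequency <- as.numeric(df$frequency)
  df$n <- as.numeric(df$n)
  if (any(df$frequency < 0)) stop("negative allele frequency", call. = FALSE)
  if (any(df$n <= 0)) stop("n (alleles sampled) must be > 0", call. = FALSE)
  if (anyDuplicated(df[c("locus", "allele")])) {
    stop("duplicate (locus, allele) rows", call. = FALSE)
  }
  sums <- tapply(df$frequency, df$locus, sum)
  if (any(abs(sums - 1) > 1e-9)) {
    bad <- names(sums)[abs(sums - 1) > 1e-9][1]
    stop(sprintf("frequencies at locus %s sum to %.6f, not 1", bad,
                 sums[[bad]]), call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, class = c("allele_freq_table", "data.frame"),
            population = population)
}

#' Read / write allele-frequency tables
#'
#' Tab-separated with header columns `locus`, `allele`, `frequency`, `n`.
#' Per-locus frequency sums within 0.5% of 1 are renormalized (with a
#' warning, as rounding in published tables routinely leaves such residue);
#' larger deviations are rejected.
#'
#' @param path file path.
#' @param population optional source-population label.
#' @return `read_frequencies()` returns an [allele_freq_table()].
#' @export
read_frequencies <- function(path, population = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, colClasses = c("character", "character",
                                               "numeric", "numeric"))
  if (any(df$frequency < 0)) stop("negative allele frequency", call. = FALSE)
  sums <- tapply(df$frequency, df$locus, sum)
  off <- abs(sums - 1)
  if (any(off > 0.005)) {
    bad <- names(sums)[off > 0.005][1]
    stop(sprintf(
      "frequencies at locus %s sum to %.4f (deviation > 0.5%%); rejected",
      bad, sums[[bad]]), call. = FALSE)
  }
  if (any(off > 1e-9)) {
    warning("renormalizing loci whose frequencies do not sum exactly to 1: ",
            paste(names(sums)[off > 1e-9], collapse = ", "), call. = FALSE)
    df$frequency <- df$frequency / as.numeric(sums[df$locus])
  }
  allele_freq_table(df, population = population)
}

#' @rdname read_frequencies
#' @param x an `allele_freq_table`.
#' @export
write_frequencies <- function(x, path) {
  stopifnot(inherits(x, "allele_freq_table"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Estimate allele frequencies from a genotype table
#'
#' Counts allele copies per locus and divides by the number of copies
#' sampled. For X loci each typed male contributes one copy and each typed
#' female two, so the pooled denominator is \eqn{n_m + 2 n_f}; `sex_mode`
#' restricts to one sex. Missing calls are excluded from denominators.
#'
#' @param x a [genotype_table()].
#' @param sex_mode `"pooled"`, `"male_only"` or `"female_only"`.
#' @param loci loci to include (default: the whole panel).
#' @return an [allele_freq_table()] with `n` = allele copies sampled.
#' @export
frequencies_from_table <- function(x,
                                   sex_mode = c("pooled", "male_only",
                                                "female_only"),
                                   loci = NULL) {
  sex_mode <- match.arg(sex_mode)
  stopifnot(inherits(x, "genotype_table"))
  if (is.null(loci)) loci <- x$panel$locus
  sex <- switch(sex_mode, pooled = "both", male_only = "M",
                female_only = "F")
  rows <- lapply(loci, function(lc) {
    cl <- locus_calls(x, lc, sex)
    alleles <- c(cl$a1, cl$a2[!is.na(cl$a2)])
    if (length(alleles) == 0L) {
      stop("no typed samples at locus ", lc,
           if (sex != "both") paste0(" for sex ", sex), call. = FALSE)
    }
    cnt <- table(alleles)
    lab <- sort_alleles(names(cnt))
    data.frame(locus = lc, allele = lab,
               frequency = as.numeric(cnt[lab]) / sum(cnt),
               n = sum(cnt), stringsAsFactors = FALSE)
  })
  pop <- unique(x$samples$population)
  allele_freq_table(do.call(rbind, rows),
                    population = if (length(pop) == 1) pop else
                      paste(pop, collapse = "+"))
}

#' Extract one locus from an allele-frequency table
#'
#' @param ft an [allele_freq_table()].
#' @param locus locus name.
#' @return `freq_vector()`: named numeric frequency vector;
#'   `locus_sample_size()`: the number of allele copies sampled.
#' @export
freq_vector <- function(ft, locus) {
  f <- ft[ft$locus == locus, , drop = FALSE]
  if (nrow(f) == 0) stop("locus not in frequency table: ", locus,
                         call. = FALSE)
  stats::setNames(f$frequency, f$allele)
}

#' @rdname freq_vector
#' @export
locus_sample_size <- function(ft, locus) {
  f <- ft[ft$locus == locus, , drop = FALSE]
  if (nrow(f) == 0) stop("locus not in frequency table: ", locus,
                         call. = FALSE)
  f$n[1]
}
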