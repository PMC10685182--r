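#' Theta-corrected single-locus random match probability
#'
#' The Balding-Nichols subpopulation-corrected conditional genotype
#' probabilities. With divergence \eqn{F} between the suspect's
#' subpopulation and the reference database population, the probability
#' that a random member of the subpopulation shares the profile genotype
#' is, for a homozygote \eqn{AA}
#' \deqn{\frac{[2F + (1-F)p_A][3F + (1-F)p_A]}{(1+F)(1+2F)}}
#' and for a heterozygote \eqn{AB}
#' \deqn{\frac{2[F + (1-F)p_A][F + (1-F)p_B]}{(1+F)(1+2F)}.}
#' At \eqn{F = 0} these reduce exactly to \eqn{p_A^2} and \eqn{2 p_A p_B}.
#'
#' @param a,b allele labels of the genotype (equal for a homozygote).
#' @param p named frequency vector of the reference database at this
#'   locus.
#' @param f divergence parameter, `0 <= f < 1`.
#' @param policy what to do when a profile allele is absent from the
#'   reference: `"strict"` errors; `"floor"` substitutes the minimum
#'   frequency `5 / (2N)` (requires `n_ref`).
#' @param n_ref allele copies behind the reference table (floor policy).
#' @return match probability in (0, 1\].
#' @export
rmp_locus <- function(a, b, p, f = 0, policy = c("strict", "floor"),
                      n_ref = NULL) {
  policy <- match.arg(policy)
  if (f < 0 || f >= 1) stop("F must satisfy 0 <= F < 1", call. = FALSE)
  get_p <- function(al) {
    val <- unname(p[al])
    if (is.na(val) || val <= 0) {
      if (policy == "strict") {
        stop(sprintf("allele %s unseen in reference database", al),
             call. = FALSE)
      }
      if (is.null(n_ref)) stop("floor policy needs n_ref", call. = FALSE)
      val <- 5 / (2 * n_ref)
    }
    val
  }
  pa <- get_p(a)
  denom <- (1 + f) * (1 + 2 * f)
  if (a == b) {
    (2 * f + (1 - f) * pa) * (3 * f + (1 - f) * pa) / denom
  } else {
    pb <- get_p(b)
    2 * (f + (1 - f) * pa) * (f + (1 - f) * pb) / denom
  }
}

#' Profile random match probability across a panel
#'
#' Product of [rmp_locus()] over the typed panel loci of one sample's
#' profile. Untyped loci are skipped (recorded in `skipped`); a profile
#' with no usable locus is an error.
#'
#' @param x a [genotype_table()].
#' @param sample_id sample whose profile is evaluated.
#' @param freqs reference [allele_freq_table()].
#' @param f divergence parameter.
#' @param loci panel loci to use (default: the autosomal panel loci).
#' @inheritParams rmp_locus
#' @return list with `sample_id`, `total` (product RMP), `per_locus`
#'   (named vector), `skipped`, `f`.
#' @export
rmp_profile <- function(x, sample_id, freqs, f = 0, loci = NULL,
                        policy = c("strict", "floor")) {
  policy <- match.arg(policy)
  stopifnot(inherits(x, "genotype_table"))
  if (is.null(loci)) {
    loci <- x$panel$locus[x$panel$chromosome == "autosomal"]
  }
  cl <- x$calls[x$calls$sample_id == sample_id & x$calls$locus %in% loci &
                  !is.na(x$calls$a2), , drop = FALSE]
  skipped <- setdiff(loci, cl$locus)
  if (nrow(cl) == 0) stop("no typed diploid panel loci for sample ",
                          sample_id, call. = FALSE)
  per <- vapply(seq_len(nrow(cl)), function(i) {
    rmp_locus(cl$a1[i], cl$a2[i], freq_vector(freqs, cl$locus[i]), f,
              policy = policy,
              n_ref = locus_sample_size(freqs, cl$locus[i]))
  }, numeric(1))
  names(per) <- cl$locus
  list(sample_id = sample_id, total = prod(per), per_locus = per,
       skipped = skipped, f = f)
}

#' Remove profiles carrying alleles unseen in a reference database
#'
#' A profile is removed when any of its alleles at a panel locus has zero
#' or absent frequency in the reference — the off-ladder screening applied
#' before auditing against a non-cognate database.
#'
#' @param x a [genotype_table()].
#' @param freqs reference [allele_freq_table()].
#' @param loci loci screened (default: autosomal panel loci).
#' @return list with `kept` (a `genotype_table`) and `removed`
#'   (data.frame `sample_id`, `locus`, `allele`).
#' @export
filter_unseen <- function(x, freqs, loci = NULL) {
  stopifnot(inherits(x, "genotype_table"))
  if (is.null(loci)) {
    loci <- x$panel$locus[x$panel$chromosome == "autosomal"]
  }
  cl <- x$calls[x$calls$locus %in% loci, , drop = FALSE]
  key <- paste(freqs$locus, freqs$allele)
  seen1 <- paste(cl$locus, cl$a1) %in% key
  seen2 <- is.na(cl$a2) | paste(cl$locus, cl$a2) %in% key
  bad <- !(seen1 & seen2)
  removed <- data.frame(
    sample_id = rep(cl$sample_id[bad], 2),
    locus = rep(cl$locus[bad], 2),
    allele = c(ifelse(seen1[bad], NA, cl$a1[bad]),
               ifelse(seen2[bad], NA, cl$a2[bad])),
    stringsAsFactors = FALSE)
  removed <- removed[!is.na(removed$allele), , drop = FALSE]
  rownames(removed) <- NULL
  drop_ids <- unique(removed$sample_id)
  keep <- !(x$samples$sample_id %in% drop_ids)
  kept <- genotype_table(
    x$samples[keep, , drop = FALSE],
    x$calls[!(x$calls$sample_id %in% drop_ids), , drop = FALSE],
    x$panel)
  list(kept = kept, removed = removed)
}

#' The d statistic
#'
#' \eqn{d = \log_{10}(RMP_{cognate} / RMP_{non\text{-}cognate})}. Positive
#' d means the non-cognate database understates the match probability and
#' therefore overstates the weight of the evidence.
#'
#' @param rmp_cognate,rmp_noncognate positive match probabilities.
#' @return d value(s).
#' @export
d_statistic <- function(rmp_cognate, rmp_noncognate) {
  if (any(rmp_cognate <= 0) || any(rmp_noncognate <= 0)) {
    stop("RMPs must be positive", call. = FALSE)
  }
  log10(rmp_cognate / rmp_noncognate)
}

#' Summarize a set of d values
#'
#' Proportion of profiles strictly exceeding each threshold (reported in
#' percent), plus mean and sample standard deviation (n-1 denominator).
#' With a single d value the SD is reported as 0 with a note.
#'
#' @param d numeric vector of d values (>= 1).
#' @param thresholds exceedance thresholds.
#' @return object of class `d_summary`: list with `n`, `thresholds`,
#'   `percent_exceeding`, `mean_d`, `sd_d`, `note`.
#' @export
d_summary <- function(d, thresholds = c(0, 0.5, 1, 2)) {
  if (length(d) < 1) stop("need >= 1 d value", call. = FALSE)
  pct <- vapply(thresholds, function(t) 100 * mean(d > t), numeric(1))
  names(pct) <- paste0("d>", thresholds)
  note <- NULL
  if (length(d) == 1) {
    sd_d <- 0
    note <- "single profile: SD undefined, reported as 0"
  } else {
    sd_d <- stats::sd(d)
  }
  structure(list(n = length(d), thresholds = thresholds,
                 percent_exceeding = pct, mean_d = mean(d), sd_d = sd_d,
                 note = note),
            class = "d_summary")
}

#' @export
print.d_summary <- function(x, ...) {
  cat(sprintf("d summary over %d profiles: %s; mean d = %.4f, SD = %.4f\n",
              x$n,
              paste(sprintf("%s: %.2f%%", names(x$percent_exceeding),
                            x$percent_exceeding), collapse = ", "),
              x$mean_d, x$sd_d))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Audit RMPs against a non-cognate database across correction levels
#'
#' For each divergence value in `f_list`, computes every profile's RMP
#' twice — against the cognate database at `f_cognate` (0 by default: a
#' cognate database needs no subpopulation correction) and against the
#' non-cognate database at that F — and summarizes the per-profile d
#' statistics. Profiles carrying alleles unseen in the non-cognate
#' database are removed first ([filter_unseen()]).
#'
#' @param x cohort [genotype_table()].
#' @param cognate_db,noncognate_db [allele_freq_table()]s.
#' @param f_list divergence values for the non-cognate calculation.
#' @param loci panel loci (default: autosomal).
#' @param f_cognate divergence used with the cognate database.
#' @return object of class `d_audit`: list with `summaries` (one
#'   [d_summary()] per F), `d_values` (matrix profiles x F), `n_removed`,
#'   `removed`, `table` (data.frame in report layout: F, percent
#'   exceedances, mean, SD).
#' @export
rmp_audit <- function(x, cognate_db, noncognate_db,
                      f_list = c(0, 0.0016, 0.0108, 0.0170),
                      loci = NULL, f_cognate = 0) {
  stopifnot(inherits(x, "genotype_table"))
  if (is.null(loci)) {
    loci <- x$panel$locus[x$panel$chromosome == "autosomal"]
  }
  flt <- filter_unseen(x, noncognate_db, loci)
  cohort <- flt$kept
  # cognate-unseen alleles would make the cognate RMP undefined too
  flt2 <- filter_unseen(cohort, cognate_db, loci)
  cohort <- flt2$kept
  ids <- cohort$samples$sample_id
  if (length(ids) == 0) stop("no profiles left after unseen-allele filtering",
                             call. = FALSE)
  rmp_cog <- vapply(ids, function(id) {
    rmp_profile(cohort, id, cognate_db, f_cognate, loci)$total
  }, numeric(1))
  dmat <- matrix(NA_real_, length(ids), length(f_list),
                 dimnames = list(ids, paste0("F=", f_list)))
  summaries <- vector("list", length(f_list))
  names(summaries) <- paste0("F=", f_list)
  for (j in seq_along(f_list)) {
    rmp_non <- vapply(ids, function(id) {
      rmp_profile(cohort, id, noncognate_db, f_list[j], loci)$total
    }, numeric(1))
    dmat[, j] <- d_statistic(rmp_cog, rmp_non)
    summaries[[j]] <- d_summary(dmat[, j])
  }
  tab <- do.call(rbind, lapply(seq_along(f_list), function(j) {
    s <- summaries[[j]]
    data.frame(F = f_list[j], t(s$percent_exceeding),
               mean_d = s$mean_d, sd_d = s$sd_d, check.names = FALSE)
  }))
  structure(list(summaries = summaries, d_values = dmat,
                 n_removed = nrow(x$samples) - length(ids),
                 removed = rbind(flt$removed, flt2$removed),
                 table = tab),
            class = "d_audit")
}

#' @export
print.d_audit <- function(x, ...) {
  cat(sprintf(
    "RMP audit over %d profiles (%d removed for unseen alleles)\n",
    nrow(x$d_values), x$n_removed))
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}
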