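#' Specify a structured-population simulation model
#'
#' Subpopulations diverge from a shared ancestral allele-frequency vector
#' under the Balding-Nichols model: subpopulation frequencies are a single
#' Dirichlet draw around the ancestral vector with divergence parameter
#' \eqn{F} (so the variance of each subpopulation frequency is
#' \eqn{F p (1 - p)}). Individuals are then sampled in Hardy-Weinberg
#' proportions within their subpopulation; X loci give two draws per female
#' and one per male.
#'
#' @param panel an [str_panel()].
#' @param ancestral named list: per locus, a named numeric vector of
#'   ancestral allele frequencies (must sum to 1).
#' @param subpops data.frame with columns `name`, `f` (divergence,
#'   `0 <= f < 1`), `n_male`, `n_female`.
#' @return object of class `population_model`.
#' @export
population_model <- function(panel, ancestral, subpops) {
  stopifnot(inherits(panel, "str_panel"))
  subpops <- as.data.frame(subpops, stringsAsFactors = FALSE)
  need <- c("name", "f", "n_male", "n_female")
  if (!all(need %in% names(subpops))) {
    stop("subpops needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(subpops$f < 0 | subpops$f >= 1)) {
    stop("divergence F must satisfy 0 <= F < 1", call. = FALSE)
  }
  if (any(subpops$n_male < 0 | subpops$n_female < 0)) {
    stop("sex counts must be >= 0", call. = FALSE)
  }
  if (!setequal(names(ancestral), panel$locus)) {
    stop("ancestral frequencies must cover exactly the panel loci",
         call. = FALSE)
  }
  for (lc in panel$locus) {
    p <- ancestral[[lc]]
    if (is.null(names(p)) || abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
      stop("invalid ancestral frequency vector at locus ", lc, call. = FALSE)
    }
  }
  structure(list(panel = panel, ancestral = ancestral, subpops = subpops),
            class = "population_model")
}

#' Draw subpopulation allele frequencies
#'
#' One Balding-Nichols draw: Dirichlet with concentrations
#' \eqn{\alpha_i = p_i (1 - F) / F}. At `f = 0` (numerically, below 1e-12)
#' the ancestral vector is returned unchanged. Alleles with ancestral
#' frequency zero are excluded (a zero Dirichlet concentration is
#' undefined) and return frequency zero.
#'
#' @param p named numeric ancestral frequency vector (sums to 1).
#' @param f divergence parameter, `0 <= f < 1`.
#' @param seed integer seed.
#' @return named numeric frequency vector summing to 1.
#' @export
draw_subpop_frequencies <- function(p, f, seed) {
  if (f >= 1) stop("F must be < 1", call. = FALSE)
  if (f < 0) stop("F must be >= 0", call. = FALSE)
  if (f < 1e-12) return(p)
  with_seed(seed, {
    q <- numeric(length(p))
    names(q) <- names(p)
    pos <- p > 0
    alpha <- p[pos] * (1 - f) / f
    g <- stats::rgamma(sum(pos), shape = alpha, rate = 1)
    if (sum(g) == 0) {
      # numerically possible only for minuscule alpha; fall back to a
      # single categorical draw
      g[sample.int(length(g), 1, prob = p[pos])] <- 1
    }
    q[pos] <- g / sum(g)
    q
  })
}

#' Simulate a structured STR population
#'
#' For every subpopulation and locus, draws the subpopulation frequency
#' vector once (shared by all its individuals — this models drift, not
#' family structure) and then samples genotypes under within-subpopulation
#' Hardy-Weinberg equilibrium. Loci are independent. Deterministic given
#' the seed.
#'
#' @param model a [population_model()].
#' @param seed integer seed.
#' @return a [genotype_table()] with samples labelled by subpopulation.
#' @export
simulate_population <- function(model, seed) {
  stopifnot(inherits(model, "population_model"))
  with_seed(seed, {
    sample_rows <- list()
    call_rows <- list()
    for (s in seq_len(nrow(model$subpops))) {
      sp <- model$subpops[s, ]
      n <- sp$n_male + sp$n_female
      if (n == 0) next
      ids <- sprintf("%s_%04d", sp$name, seq_len(n))
      sex <- c(rep("M", sp$n_male), rep("F", sp$n_female))
      sample_rows[[length(sample_rows) + 1L]] <- data.frame(
        sample_id = ids, sex = sex, population = sp$name,
        stringsAsFactors = FALSE)
      for (lc in model$panel$locus) {
        p <- model$ancestral[[lc]]
        q <- draw_subpop_frequencies(
          p, sp$f, stats::runif(1, 0, .Machine$integer.max))
        labs <- names(q)
        xlink <- panel_class(model$panel, lc) == "X"
        n_copies <- if (xlink) as.integer(sex == "F") + 1L else
          rep(2L, n)
        draws <- sample(labs, sum(n_copies), replace = TRUE, prob = q)
        a1 <- character(n); a2 <- rep(NA_character_, n)
        pos <- cumsum(n_copies)
        a1 <- draws[pos - n_copies + 1L]
        two <- n_copies == 2L
        a2[two] <- draws[pos[two]]
        call_rows[[length(call_rows) + 1L]] <- data.frame(
          sample_id = ids, locus = lc, a1 = a1, a2 = a2,
          stringsAsFactors = FALSE)
      }
    }
    genotype_table(do.call(rbind, sample_rows), do.call(rbind, call_rows),
                   model$panel)
  })
}

#' Inject alleles unseen in a reference database
#'
#' Emulates profiles carrying off-ladder (OL) alleles absent from a
#' reference frequency database: for a Bernoulli(`rate`) subset of samples,
#' one randomly chosen call has one allele replaced by the OL sentinel,
#' which no reference table contains.
#'
#' @param x a [genotype_table()].
#' @param rate per-sample probability of gaining an unseen allele.
#' @param seed integer seed.
#' @return a modified `genotype_table`.
#' @export
inject_unseen_alleles <- function(x, rate, seed) {
  stopifnot(inherits(x, "genotype_table"))
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]", call. = FALSE)
  if (rate == 0) return(x)
  with_seed(seed, {
    hit <- stats::rbinom(nrow(x$samples), 1, rate) == 1
    calls <- x$calls
    for (id in x$samples$sample_id[hit]) {
      idx <- which(calls$sample_id == id)
      if (length(idx) == 0) next
      j <- idx[sample.int(length(idx), 1)]
      if (!is.na(calls$a2[j]) && stats::runif(1) < 0.5) {
        calls$a2[j] <- "OL"
      } else {
        calls$a1[j] <- "OL"
      }
    }
    genotype_table(x$samples, calls, x$panel)
  })
}

# ---- bundled demo study conditions ----------------------------------------

demo_autosomal_loci <- c(
  "CSF1PO", "D10S1248", "D12S391", "D13S317", "D16S539", "D18S51",
  "D19S433", "D21S11", "D2S1338", "D2S441", "D3S1358", "D5S818",
  "D6S1043", "D7S820", "D8S1179", "FGA", "PentaD", "PentaE", "TH01",
  "TPOX", "vWA")

demo_x_loci <- c(
  "DXS8378", "DXS9898", "DXS7133", "GATA31E08", "GATA172D05", "DXS10159",
  "DXS10134", "DXS10074", "DXS7423", "DXS10164", "DXS10162", "HPRTB",
  "DXS6809", "DXS10103", "DXS10101", "DXS10079", "DXS6800", "DXS101",
  "DXS10135")

#' Bundled demo panel and population model
#'
#' A 21-autosomal + 19-X STR panel with per-locus allele counts between 5
#' (DXS7133, DXS7423) and 22 (DXS10135) and ancestral frequencies drawn
#' once from a symmetric Dirichlet, clipped to the range 0.0025-0.85 — the
#' frequency range typical of published forensic STR databases. The default
#' model holds two subpopulations diverged from the ancestral vector at
#' F = 0.01 each: a cognate cohort of 333 males and 88 females and a large
#' non-cognate reference population of 2793 individuals.
#'
#' @return `demo_panel()`: an [str_panel()]; `demo_model()`: a
#'   [population_model()].
#' @export
demo_panel <- function() {
  str_panel(c(demo_autosomal_loci, demo_x_loci),
            c(rep("autosomal", length(demo_autosomal_loci)),
              rep("X", length(demo_x_loci))))
}

#' @rdname demo_panel
#' @param f per-subpopulation divergence from the ancestral frequencies.
#' @export
demo_model <- function(f = 0.01) {
  panel <- demo_panel()
  n_alleles <- stats::setNames(integer(nrow(panel)), panel$locus)
  with_seed(903151, {
    n_alleles[demo_autosomal_loci] <-
      sample(7:20, length(demo_autosomal_loci), replace = TRUE)
    n_alleles[demo_x_loci] <- sample(6:18, length(demo_x_loci),
                                     replace = TRUE)
    n_alleles[c("DXS7133", "DXS7423")] <- 5L
    n_alleles["DXS10135"] <- 22L
    ancestral <- lapply(panel$locus, function(lc) {
      k <- n_alleles[[lc]]
      p <- stats::rgamma(k, shape = 1.5, rate = 1)
      p <- p / sum(p)
      p <- pmin(pmax(p, 0.0025), 0.85)
      p <- p / sum(p)
      labs <- as.character(seq(6L, length.out = k))
      if (lc %in% c("TH01", "D6S1043")) labs[k - 1L] <-
        paste0(labs[k - 1L], ".3")
      stats::setNames(p, labs)
    })
  })
  names(ancestral) <- panel$locus
  population_model(
    panel, ancestral,
    data.frame(name = c("QiangLike", "HanLike"), f = f,
               n_male = c(333L, 1397L), n_female = c(88L, 1396L),
               stringsAsFactors = FALSE))
}
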