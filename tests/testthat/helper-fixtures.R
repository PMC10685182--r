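# Small in-code fixtures shared across the suite.

toy_panel <- function() {
  str_panel(c("AUT1", "AUT2", "XL1", "XL2"),
            c("autosomal", "autosomal", "X", "X"))
}

# genotype table built directly from vectors of "a/b" (diploid) or "a"
# (hemizygous) strings; NA = missing call
toy_table <- function(calls, sex, population = "P1", panel = toy_panel()) {
  ids <- sprintf("S%03d", seq_along(sex))
  rows <- list()
  for (lc in names(calls)) {
    v <- calls[[lc]]
    for (i in seq_along(v)) {
      if (is.na(v[i])) next
      parts <- strsplit(v[i], "/", fixed = TRUE)[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = ids[i], locus = lc, a1 = parts[1],
        a2 = if (length(parts) == 2) parts[2] else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  genotype_table(
    data.frame(sample_id = ids, sex = sex, population = population,
               stringsAsFactors = FALSE),
    do.call(rbind, rows), panel)
}

# frequency table from a named list locus -> named freq vector
toy_freqs <- function(freqs, n = 400, population = "REF") {
  rows <- lapply(names(freqs), function(lc) {
    data.frame(locus = lc, allele = names(freqs[[lc]]),
               frequency = as.numeric(freqs[[lc]]), n = n,
               stringsAsFactors = FALSE)
  })
  allele_freq_table(do.call(rbind, rows), population = population)
}

# random frequency vector of k alleles (STR-style labels)
random_freqs <- function(k, alpha = 1) {
  p <- rgamma(k, alpha)
  p <- p / sum(p)
  names(p) <- as.character(seq(8, length.out = k))
  p
}

# small two-population Balding-Nichols model over `n_loci` autosomal loci
bn_model <- function(n_loci, k_alleles, f, n_per_pop,
                     names_ = c("A", "B"), freq_seed = 77) {
  panel <- str_panel(sprintf("L%03d", seq_len(n_loci)), "autosomal")
  ancestral <- strpop:::with_seed(freq_seed, {
    lapply(seq_len(n_loci), function(i) random_freqs(k_alleles, 1.5))
  })
  names(ancestral) <- panel$locus
  population_model(
    panel, ancestral,
    data.frame(name = names_, f = f,
               n_male = n_per_pop, n_female = 0L,
               stringsAsFactors = FALSE))
}
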