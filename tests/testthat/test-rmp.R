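test_that("single-locus RMP matches direct substitution", {
  expect_equal(rmp_locus("A", "A", c(A = 0.5), 0), 0.25)
  expect_equal(rmp_locus("A", "B", c(A = 0.5, B = 0.5), 0), 0.5)
  expect_equal(rmp_locus("A", "A", c(A = 0.1), 0.01),
               (0.119 * 0.129) / 1.0302, tolerance = 1e-12)
  expect_equal(rmp_locus("A", "B", c(A = 0.1, B = 0.2), 0.01),
               2 * 0.109 * 0.208 / 1.0302, tolerance = 1e-12)
})

test_that("theta-corrected RMP has the right limits", {
  # F = 0 reduces exactly to p^2 and 2 p q over a grid
  grid <- seq(0.005, 0.99, length.out = 100)
  for (pa in grid) {
    expect_equal(rmp_locus("A", "A", c(A = pa), 0), pa^2,
                 tolerance = 1e-15)
    pb <- (1 - pa) / 2
    expect_equal(rmp_locus("A", "B", c(A = pa, B = pb), 0), 2 * pa * pb,
                 tolerance = 1e-15)
  }
  # homozygote probability approaches 1 as F -> 1 regardless of p
  for (pa in c(0.01, 0.3, 0.9)) {
    expect_equal(rmp_locus("A", "A", c(A = pa), 1 - 1e-9), 1,
                 tolerance = 1e-6)
  }
  expect_error(rmp_locus("A", "A", c(A = 0.5), 1), "F must")
})

test_that("RMP is increasing in F for rare-allele genotypes", {
  fs <- seq(0, 0.05, length.out = 21)
  for (p in list(c(A = 0.05), c(A = 0.2))) {
    v <- vapply(fs, function(f) rmp_locus("A", "A", p, f), numeric(1))
    expect_true(all(diff(v) > 0))
  }
  v <- vapply(fs, function(f) {
    rmp_locus("A", "B", c(A = 0.1, B = 0.25), f)
  }, numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("profile RMP multiplies across typed loci", {
  tab <- toy_table(list(AUT1 = c("10/11"), AUT2 = c("12/12")), sex = "F")
  freqs <- toy_freqs(list(AUT1 = c("10" = 0.2, "11" = 0.3, "12" = 0.5),
                          AUT2 = c("12" = 0.4, "13" = 0.6)))
  r1 <- rmp_profile(tab, "S001", freqs, 0, loci = "AUT1")
  expect_equal(r1$total, 2 * 0.2 * 0.3)
  r <- rmp_profile(tab, "S001", freqs, 0)
  expect_equal(r$total, (2 * 0.2 * 0.3) * 0.4^2)
  expect_equal(r$total, prod(r$per_locus))
  # untyped loci are skipped; an all-untyped profile errors
  tab2 <- toy_table(list(AUT1 = c("10/11", NA)), sex = c("F", "F"))
  r2 <- rmp_profile(tab2, "S001", freqs)
  expect_equal(r2$skipped, "AUT2")
  expect_error(rmp_profile(tab2, "S002", freqs), "no typed")
})

test_that("unseen alleles follow the configured policy", {
  freqs <- toy_freqs(list(AUT1 = c("10" = 1)), n = 200)
  expect_error(rmp_locus("10", "11", freq_vector(freqs, "AUT1"), 0),
               "unseen")
  floor_val <- rmp_locus("10", "11", freq_vector(freqs, "AUT1"), 0,
                         policy = "floor", n_ref = 200)
  expect_equal(floor_val, 2 * 1 * (5 / 400))
})

test_that("profiles with database-absent alleles are screened out", {
  calls <- list(AUT1 = rep("10/11", 205), AUT2 = rep("12/13", 205))
  calls$AUT1[8] <- "10/OL"
  calls$AUT2[c(30, 44, 59, 101, 140, 160, 180, 201)] <- "12/99"
  tab <- toy_table(calls, sex = rep("F", 205))
  freqs <- toy_freqs(list(AUT1 = c("10" = 0.5, "11" = 0.5),
                          AUT2 = c("12" = 0.5, "13" = 0.5)))
  flt <- filter_unseen(tab, freqs)
  expect_equal(nrow(flt$kept$samples), 196)
  expect_equal(length(unique(flt$removed$sample_id)), 9)
  expect_true(all(c("locus", "allele") %in% names(flt$removed)))
  # a fully covered cohort is untouched
  tab_ok <- toy_table(list(AUT1 = rep("10/11", 5)), sex = rep("F", 5))
  flt_ok <- filter_unseen(tab_ok, freqs)
  expect_equal(nrow(flt_ok$kept$samples), 5)
  expect_equal(nrow(flt_ok$removed), 0)
})

test_that("the d statistic follows the log10-ratio convention", {
  expect_equal(d_statistic(1e-8, 1e-8), 0)
  expect_equal(d_statistic(1e-8, 1e-10), 2)
  expect_equal(d_statistic(1e-10, 1e-8), -2)
  expect_error(d_statistic(0, 1e-8), "positive")
})

test_that("d summaries report exceedance percentages and moments", {
  d <- c(-0.5, 0.2, 0.7, 1.5, 2.5)
  s <- d_summary(d)
  expect_equal(unname(s$percent_exceeding), c(80, 60, 40, 20))
  expect_equal(s$mean_d, 0.88)
  expect_equal(s$sd_d, 1.1628, tolerance = 1e-4)
  s0 <- d_summary(rep(0, 4))
  expect_equal(unname(s0$percent_exceeding), rep(0, 4))
  expect_equal(s0$sd_d, 0)
  s1 <- d_summary(1)
  expect_equal(unname(s1$percent_exceeding), c(100, 100, 0, 0))
  expect_equal(s1$sd_d, 0)
  expect_match(s1$note, "single")
  # proportions never increase with the threshold
  set.seed(2)
  for (i in 1:20) {
    s <- d_summary(rnorm(50))
    expect_true(all(diff(s$percent_exceeding) <= 0))
  }
})

test_that("a self-audit against the cognate database is neutral", {
  model <- bn_model(12, 6, f = 0.01, n_per_pop = 60)
  tab <- simulate_population(model, 61)
  cohort <- subset_population(tab, "A")
  db <- frequencies_from_table(cohort, "pooled")
  audit <- rmp_audit(cohort, db, db, f_list = 0)
  expect_equal(audit$summaries[["F=0"]]$mean_d, 0)
  expect_equal(unname(audit$summaries[["F=0"]]$percent_exceeding["d>0"]), 0)
})
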