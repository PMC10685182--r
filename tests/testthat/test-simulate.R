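test_that("zero divergence returns the ancestral vector unchanged", {
  p <- c(A = 0.5, B = 0.5)
  expect_identical(draw_subpop_frequencies(p, 0, 1), p)
  expect_error(draw_subpop_frequencies(p, 1, 1), "< 1")
})

test_that("subpopulation frequencies have Balding-Nichols moments", {
  p <- c(A = 0.3, B = 0.7)
  f <- 0.01
  q1 <- vapply(seq_len(10000), function(i) {
    draw_subpop_frequencies(p, f, 5000 + i)[["A"]]
  }, numeric(1))
  # Dirichlet mean = p, variance = f * p (1 - p) (alpha0 = (1-f)/f)
  se_mean <- sqrt(f * 0.3 * 0.7 / 10000)
  expect_lt(abs(mean(q1) - 0.3), 3 * se_mean)
  expect_lt(abs(var(q1) - f * 0.3 * 0.7), 0.1 * f * 0.3 * 0.7)
})

test_that("simulation respects ploidy, fixation and determinism", {
  panel <- str_panel(c("A1", "X1"), c("autosomal", "X"))
  model <- population_model(
    panel, list(A1 = c("10" = 1), X1 = c("12" = 0.4, "13" = 0.6)),
    data.frame(name = "P", f = 0, n_male = 20, n_female = 10))
  tab <- simulate_population(model, 42)
  a1 <- tab$calls[tab$calls$locus == "A1", ]
  expect_true(all(a1$a1 == "10" & a1$a2 == "10"))  # fixed allele
  sex <- tab$samples$sex[match(tab$calls$sample_id, tab$samples$sample_id)]
  x_m <- tab$calls$locus == "X1" & sex == "M"
  expect_true(all(is.na(tab$calls$a2[x_m])))       # hemizygous males
  expect_true(all(!is.na(tab$calls$a2[tab$calls$locus == "X1" & sex == "F"])))
  # same seed => identical tables; different seed => different draws
  expect_identical(simulate_population(model, 42), tab)
  tab2 <- simulate_population(model, 43)
  expect_false(identical(tab2$calls, tab$calls))
})

test_that("large-sample genotype proportions satisfy HWE", {
  panel <- str_panel("A1", "autosomal")
  p <- c("10" = 0.3, "11" = 0.7)
  model <- population_model(
    panel, list(A1 = p),
    data.frame(name = "P", f = 0, n_male = 5000, n_female = 0))
  tab <- simulate_population(model, 7)
  g <- tab$calls
  counts <- table(paste(pmin(g$a1, g$a2), pmax(g$a1, g$a2)))
  expected <- c(5000 * 0.09, 2 * 5000 * 0.21, 5000 * 0.49)
  chi2 <- sum((as.numeric(counts[c("10 10", "10 11", "11 11")]) -
                 expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, df = 2))
})

test_that("unseen-allele injection hits the requested samples", {
  tab <- toy_table(list(AUT1 = rep("10/11", 10), AUT2 = rep("12/12", 10)),
                   sex = rep("F", 10))
  expect_identical(inject_unseen_alleles(tab, 0, 1), tab)
  tab1 <- inject_unseen_alleles(tab, 1, 1)
  hit <- tapply(tab1$calls$a1 == "OL" |
                  (!is.na(tab1$calls$a2) & tab1$calls$a2 == "OL"),
                tab1$calls$sample_id, any)
  expect_true(all(hit))
  # reproducible at intermediate rates
  t_a <- inject_unseen_alleles(tab, 0.4, 9)
  t_b <- inject_unseen_alleles(tab, 0.4, 9)
  expect_identical(t_a, t_b)
})

test_that("the bundled demo model matches its documented shape", {
  model <- demo_model()
  expect_equal(nrow(model$panel), 40)
  expect_equal(sum(model$panel$chromosome == "X"), 19)
  k <- vapply(model$ancestral, length, integer(1))
  expect_equal(unname(k[c("DXS7133", "DXS7423", "DXS10135")]),
               c(5L, 5L, 22L))
  expect_true(all(k >= 5 & k <= 22))
  rng <- range(unlist(model$ancestral))
  expect_gte(rng[1], 0.0025 / 2)  # renormalization after clipping
  expect_lte(rng[2], 0.86)
  expect_equal(model$subpops$n_male[model$subpops$name == "QiangLike"], 333)
  expect_equal(model$subpops$n_female[model$subpops$name == "QiangLike"], 88)
})
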