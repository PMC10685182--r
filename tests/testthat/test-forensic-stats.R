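test_that("heterozygosities match hand-computed values", {
  expect_equal(heterozygosities(rbind(c("A", "B"), c("A", "B"))),
               c(Ho = 1, He = (4 / 3) * 0.5), tolerance = 1e-12)
  expect_equal(heterozygosities(rbind(c("A", "A"), c("A", "A"))),
               c(Ho = 0, He = 0))
  g <- rbind(c("A", "A"), c("A", "B"), c("B", "B"), c("A", "B"))
  expect_equal(heterozygosities(g), c(Ho = 0.5, He = (8 / 7) * 0.5),
               tolerance = 1e-12)
  expect_error(heterozygosities(rbind(c("A", "B"))), "at least 2")
})

test_that("PIC matches the power-sum polynomial", {
  expect_equal(pic(1), 0)
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(pic(rep(0.25, 4)), 0.703125)
})

test_that("match probability agrees between counting and HWE modes", {
  g <- rbind(c("A", "A"), c("A", "B"), c("A", "B"), c("B", "B"))
  expect_equal(match_probability(g, mode = "observed"),
               c(MP = 0.375, PD = 0.625))
  expect_equal(match_probability(p = c(0.5, 0.5), mode = "expected"),
               c(MP = 0.375, PD = 0.625))
  g1 <- rbind(c("A", "A"), c("A", "A"))
  expect_equal(match_probability(g1, mode = "observed"), c(MP = 1, PD = 0))
})

test_that("PE and TPI follow the heterozygote-fraction formulas", {
  g <- rbind(c("A", "B"), c("A", "A"))  # Ho = 0.5
  expect_equal(suppressWarnings(exclusion_and_tpi(g)),
               c(PE = 0.25 * (1 - 2 * 0.5 * 0.25), TPI = 1))
  g0 <- rbind(c("A", "A"), c("B", "B"))  # Ho = 0
  expect_equal(exclusion_and_tpi(g0), c(PE = 0, TPI = 0.5))
  g1 <- rbind(c("A", "B"), c("A", "B"))  # Ho = 1
  expect_warning(res <- exclusion_and_tpi(g1), "infinite")
  expect_equal(res[["PE"]], 1)
  expect_equal(res[["TPI"]], Inf)
})

test_that("X discrimination equals the HWE genotype-sum oracle", {
  for (p in list(c(0.5, 0.5), rep(0.25, 4))) {
    xd <- x_discrimination(p)
    # oracle: enumerate female HWE genotype probabilities
    k <- length(p)
    gp <- c()
    for (i in 1:k) for (j in i:k) {
      gp <- c(gp, if (i == j) p[i]^2 else 2 * p[i] * p[j])
    }
    expect_equal(xd[["PD_female"]], 1 - sum(gp^2), tolerance = 1e-12)
    expect_equal(xd[["PD_male"]], 1 - sum(p^2), tolerance = 1e-12)
  }
  expect_equal(x_discrimination(c(0.5, 0.5))[["PD_female"]], 0.625)
  expect_equal(x_discrimination(rep(0.25, 4))[["PD_female"]], 0.890625)
  expect_equal(unname(x_discrimination(1)[c("PD_male", "PD_female")]),
               c(0, 0))
  expect_equal(x_discrimination(c(0.5, 0.5), n = 100)[["HD"]],
               100 / 99 * 0.5)
})

test_that("combination rules multiply across independent loci", {
  two <- combine_forensic(mp = c(0.1, 0.1), pe = c(0.5, 0.5))
  expect_equal(two$CPD, 0.99)
  expect_equal(two$CPE, 0.75)
  one <- combine_forensic(mp = 0.3, pe = 0.4)
  expect_equal(one$CPM, 0.3)
  expect_equal(one$CPE, 0.4)
  # adding a locus never decreases CPD or CPE
  set.seed(31)
  mp <- runif(8, 0.01, 0.9)
  pe <- runif(8, 0.01, 0.9)
  for (m in 2:8) {
    expect_gte(combine_forensic(mp = mp[1:m])$CPD,
               combine_forensic(mp = mp[1:(m - 1)])$CPD)
    expect_gte(combine_forensic(pe = pe[1:m])$CPE,
               combine_forensic(pe = pe[1:(m - 1)])$CPE)
  }
})

test_that("forensic parameters are invariant under allele relabeling", {
  set.seed(5)
  g <- cbind(sample(as.character(8:12), 40, TRUE),
             sample(as.character(8:12), 40, TRUE))
  relab <- setNames(as.character(20:24), as.character(8:12))
  g2 <- cbind(relab[g[, 1]], relab[g[, 2]])
  expect_equal(heterozygosities(g), heterozygosities(g2))
  expect_equal(match_probability(g), match_probability(g2))
  expect_equal(exclusion_and_tpi(g), exclusion_and_tpi(g2))
  p <- as.numeric(table(g)) / (2 * nrow(g))
  expect_equal(pic(p), pic(rev(p)))
  expect_equal(mec(p, "AUTOSOMAL_TRIO"), mec(rev(p), "AUTOSOMAL_TRIO"))
})

test_that("the per-locus summary table is coherent", {
  set.seed(11)
  model <- demo_model(0)
  model$subpops <- model$subpops[1, ]
  tab <- simulate_population(model, 3)
  sm <- forensic_summary(tab, loci = c("vWA", "TH01", "DXS10135", "DXS7133"))
  expect_equal(sm$PD, 1 - sm$MP, tolerance = 1e-12)
  expect_true(all(sm$Ho >= 0 & sm$Ho <= 1))
  expect_true(all(sm$He >= 0 & sm$He <= 1))
  x <- sm[sm$chromosome == "X", ]
  expect_true(all(x$MEC_x_duo <= x$MEC_x_trio))
  comb <- attr(sm, "combined")
  expect_equal(comb$CPD, 1 - comb$CPM, tolerance = 1e-12)
  expect_gte(comb$CPE, max(sm$PE[sm$chromosome == "autosomal"]))
})
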