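xx_panel <- function() str_panel(c("X1", "X2"), "X")

male_hap_table <- function(h1, h2) {
  ids <- sprintf("M%04d", seq_along(h1))
  genotype_table(
    data.frame(sample_id = ids, sex = "M", population = "P"),
    rbind(data.frame(sample_id = ids, locus = "X1", a1 = h1, a2 = NA),
          data.frame(sample_id = ids, locus = "X2", a1 = h2, a2 = NA)),
    xx_panel())
}

test_that("perfectly coupled loci reach the minimal permutation p", {
  set.seed(1)
  h1 <- sample(c("15", "16"), 120, TRUE)
  h2 <- ifelse(h1 == "15", "20", "21")
  tab <- male_hap_table(h1, h2)
  res <- ld_test(tab, c("X1", "X2"), sex = "M", n_perm = 300, seed = 2)
  expect_equal(res$p_value, 1 / 301)
  expect_error(ld_test(tab, c("X1", "X2"), sex = "M", n_perm = 50), ">= 100")
})

test_that("male haplotype frequencies count directly", {
  tab <- male_hap_table(c("16", "16"), c("20", "20"))
  hf <- haplotype_frequencies(tab, c("X1", "X2"))
  expect_equal(hf$haplotype, "16-20")
  expect_equal(hf$frequency, 1)
  tab2 <- male_hap_table(c("15", "16", "16"), c("20", "20", "21"))
  hf2 <- haplotype_frequencies(tab2, c("X1", "X2"))
  expect_setequal(hf2$haplotype, c("15-20", "16-20", "16-21"))
  expect_equal(hf2$frequency, rep(1 / 3, 3))
  expect_equal(sum(hf2$frequency), 1)
})

test_that("sampled haplotype frequencies recover the truth", {
  set.seed(8)
  haps <- c("15-20", "15-21", "16-20", "16-21")
  truth <- c(0.4, 0.1, 0.1, 0.4)
  draw <- sample(haps, 5000, TRUE, truth)
  parts <- do.call(rbind, strsplit(draw, "-"))
  tab <- male_hap_table(parts[, 1], parts[, 2])
  hf <- haplotype_frequencies(tab, c("X1", "X2"))
  est <- setNames(hf$frequency, hf$haplotype)[haps]
  se <- sqrt(truth * (1 - truth) / 5000)
  expect_true(all(abs(est - truth) < 3 * se))
})

test_that("the type-I error of the male permutation test is controlled", {
  set.seed(90)
  pvals <- vapply(1:60, function(r) {
    h1 <- sample(as.character(14:18), 250, TRUE)
    h2 <- sample(as.character(20:24), 250, TRUE)
    ld_test(male_hap_table(h1, h2), c("X1", "X2"), sex = "M",
            n_perm = 400, seed = 1000 + r)$p_value
  }, numeric(1))
  # under independence p <= 0.01 should be rare: binomial(60, 0.01)
  # exceeds 4 rejections with probability < 3e-4
  expect_lte(sum(pvals <= 0.01), 4)
  expect_gte(mean(pvals > 0.01), 0.9)
})

test_that("EM recovers known haplotype frequencies from female genotypes", {
  set.seed(13)
  haps <- expand.grid(a = c("15", "16"), b = c("20", "21"),
                      stringsAsFactors = FALSE)
  truth <- c(0.4, 0.1, 0.1, 0.4)  # coupling LD
  n <- 500
  pick <- function() haps[sample.int(4, 2, TRUE, truth), ]
  g <- replicate(n, pick(), simplify = FALSE)
  ids <- sprintf("F%04d", 1:n)
  calls <- do.call(rbind, lapply(seq_len(n), function(i) {
    h <- g[[i]]
    rbind(data.frame(sample_id = ids[i], locus = "X1",
                     a1 = h$a[1], a2 = h$a[2]),
          data.frame(sample_id = ids[i], locus = "X2",
                     a1 = h$b[1], a2 = h$b[2]))
  }))
  tab <- genotype_table(
    data.frame(sample_id = ids, sex = "F", population = "P"),
    calls, xx_panel())
  res <- ld_test(tab, c("X1", "X2"), sex = "F", n_perm = 100, seed = 4)
  est <- res$haplotypes
  expect_lt(abs(est[["15", "20"]] - 0.4), 0.05)
  expect_lt(abs(est[["16", "21"]] - 0.4), 0.05)
  expect_lt(abs(est[["15", "21"]] - 0.1), 0.05)
  expect_equal(sum(est), 1, tolerance = 1e-6)
  # strong coupling should be detected
  expect_lte(res$p_value, 0.02)
})
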