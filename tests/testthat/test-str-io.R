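test_that("wide files are read with correct allele counting", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tsex\tpopulation\tAUT1_1\tAUT1_2",
               "S1\tM\tP1\t15\t16",
               "S2\tF\tP1\t15\t15"), path)
  tab <- read_genotypes(path, toy_panel(), "wide")
  expect_equal(nrow(tab$samples), 2)
  ft <- frequencies_from_table(tab, loci = "AUT1")
  expect_equal(freq_counts <- setNames(ft$frequency * ft$n, ft$allele),
               c("15" = 3, "16" = 1))
})

test_that("long files carry hemizygous male X calls as single rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tsex\tpopulation\tlocus\tallele",
               "S1\tM\tP1\tXL1\t22"), path)
  tab <- read_genotypes(path, toy_panel(), "long")
  expect_equal(nrow(tab$calls), 1)
  expect_true(is.na(tab$calls$a2))
  expect_equal(tab$calls$a1, "22")
})

test_that("malformed labels and two-allele male X calls are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tsex\tpopulation\tAUT1_1\tAUT1_2",
               "S1\tM\tP1\tABC\t16"), path)
  expect_error(read_genotypes(path, toy_panel(), "wide"),
               "malformed allele label 'ABC' \\(sample S1")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tsex\tpopulation\tXL1_1\tXL1_2",
               "S1\tM\tP1\t15\t16"), path2)
  expect_error(read_genotypes(path2, toy_panel(), "wide"),
               "two distinct alleles at X locus")
  # a duplicated identical allele collapses to one hemizygous copy
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tsex\tpopulation\tXL1_1\tXL1_2",
               "S1\tM\tP1\t15\t15"), path3)
  tab <- read_genotypes(path3, toy_panel(), "wide")
  expect_true(is.na(tab$calls$a2))
})

test_that("genotype tables round-trip through both dialects", {
  tab <- toy_table(
    list(AUT1 = c("15/16", "15/15", NA), AUT2 = c("9.3/10", "10/10", "9/9"),
         XL1 = c("22", "15/16", "13")),
    sex = c("M", "F", "M"))
  for (dialect in c("wide", "long")) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_genotypes(tab, path, dialect)
    back <- read_genotypes(path, toy_panel(), dialect)
    o <- order(back$calls$sample_id, back$calls$locus)
    o0 <- order(tab$calls$sample_id, tab$calls$locus)
    expect_equal(back$calls[o, ], tab$calls[o0, ], ignore_attr = TRUE)
    expect_equal(back$samples, tab$samples, ignore_attr = TRUE)
  }
})

test_that("frequency tables renormalize small deficits and reject large ones", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus\tallele\tfrequency\tn",
               "L\tA\t0.75\t400", "L\tB\t0.25\t400"), path)
  ft <- read_frequencies(path)
  expect_s3_class(ft, "allele_freq_table")
  expect_equal(sum(ft$frequency), 1)

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus\tallele\tfrequency\tn",
               "L\tA\t0.75\t400", "L\tB\t0.248\t400"), path2)
  expect_warning(ft2 <- read_frequencies(path2), "renormalizing")
  expect_equal(sum(ft2$frequency), 1, tolerance = 1e-12)

  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus\tallele\tfrequency\tn",
               "L\tA\t0.75\t400", "L\tB\t0.15\t400"), path3)
  expect_error(read_frequencies(path3), "rejected")

  path4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus\tallele\tfrequency\tn",
               "L\tA\t1.2\t400", "L\tB\t-0.2\t400"), path4)
  expect_error(read_frequencies(path4), "negative")
})

test_that("frequency estimation follows the hemizygous pooling rules", {
  tab <- toy_table(list(XL1 = c("15", "15/16")), sex = c("M", "F"))
  ft <- frequencies_from_table(tab, "pooled", "XL1")
  expect_equal(freq_vector(ft, "XL1"), c("15" = 2 / 3, "16" = 1 / 3))
  expect_equal(locus_sample_size <- ft$n[1], 3)

  tab2 <- toy_table(list(AUT1 = c("10/10", "10/11")), sex = c("M", "F"))
  ft2 <- frequencies_from_table(tab2, loci = "AUT1")
  expect_equal(freq_vector(ft2, "AUT1"), c("10" = 0.75, "11" = 0.25))
  expect_equal(ft2$n[1], 4)

  tab3 <- toy_table(list(XL1 = c("15", "15", "17")), sex = c("M", "M", "M"))
  ft3 <- frequencies_from_table(tab3, "male_only", "XL1")
  expect_equal(freq_vector(ft3, "XL1"), c("15" = 2 / 3, "17" = 1 / 3))

  # zero typed samples is an error, and sums are exact for typed loci
  tab4 <- toy_table(list(AUT1 = c("10/10", NA)), sex = c("M", "F"))
  expect_error(frequencies_from_table(tab4, loci = "AUT2"), "no typed")
  expect_equal(sum(frequencies_from_table(tab4, loci = "AUT1")$frequency), 1,
               tolerance = 1e-12)
})

test_that("frequency tables round-trip exactly", {
  ft <- toy_freqs(list(L1 = c(A = 0.25, B = 0.75),
                       L2 = c("9.3" = 0.5, "10" = 0.5)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_frequencies(ft, path)
  back <- read_frequencies(path, population = "REF")
  expect_equal(as.data.frame(back), as.data.frame(ft), ignore_attr = TRUE)
})

test_that("panel configuration round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_panel(toy_panel(), path)
  expect_equal(read_panel(path), toy_panel(), ignore_attr = TRUE)
})
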