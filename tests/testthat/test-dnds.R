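base20 <- strrep("ATGGCTGAAGCTGAAGCTAAAGCTGAAGCTAAAGCTGAAGCTAAAGCTGAAGCTAAAGCT", 1)

test_that("single synonymous and nonsynonymous changes are classified", {
  # 20 codons, one third-position synonymous change (GCT -> GCC, both Ala)
  a <- base20
  b <- sub("GCT", "GCC", a)
  syn <- nei_gojobori_dnds(c(a = a, b = b))
  expect_equal(syn$Nd, 0)
  expect_gt(syn$Sd, 0)
  expect_equal(syn$dn, 0)
  expect_gt(syn$ds, 0)
  # one first-position nonsynonymous change (GCT -> CCT, Ala -> Pro)
  d <- sub("GCT", "CCT", a)
  non <- nei_gojobori_dnds(c(a = a, b = d))
  expect_equal(non$Sd, 0)
  expect_gt(non$Nd, 0)
  expect_equal(non$ds, 0)
  expect_false(non$ratio_defined)
  expect_true(is.na(non$ratio))
})

test_that("identical sequences give zero distances and an undefined ratio", {
  res <- nei_gojobori_dnds(c(a = base20, b = base20))
  expect_equal(res$dn, 0)
  expect_equal(res$ds, 0)
  expect_false(res$ratio_defined)
})

test_that("codons with gaps or ambiguity are skipped and frame errors caught", {
  res <- nei_gojobori_dnds(c(a = "ATGGCTAAA", b = "ATG---AAA"))
  expect_equal(res$codons_used, 2)   # the deleted codon is dropped
  resN <- nei_gojobori_dnds(c(a = "ATGGNT", b = "ATGGCT"))
  expect_equal(resN$codons_used, 1)
  expect_error(nei_gojobori_dnds(c(a = "ATG")), "at least two")
  expect_error(nei_gojobori_dnds(c(a = "ATG", b = "ATG"), region = integer(0)),
               "at least one")
})

test_that("site and difference counts match a brute-force pathway oracle", {
  set.seed(12)
  codons <- apply(expand.grid(ORACLE_BASES, ORACLE_BASES, ORACLE_BASES),
                  1, paste, collapse = "")
  sense <- setdiff(codons, ORACLE_STOPS)
  for (i in 1:60) {
    c1 <- sample(sense, 1)
    c2 <- sample(sense, 1)
    res <- nei_gojobori_dnds(c(a = c1, b = c2))
    st1 <- oracle_ng_codon_sites(c1)
    st2 <- oracle_ng_codon_sites(c2)
    d <- oracle_ng_codon_diffs(c1, c2)
    expect_equal(res$S, unname((st1["syn"] + st2["syn"]) / 2),
                 tolerance = 1e-12, info = paste(c1, c2))
    expect_equal(res$Sd, unname(d["sd"]), tolerance = 1e-12,
                 info = paste(c1, c2))
    expect_equal(res$Nd, unname(d["nd"]), tolerance = 1e-12,
                 info = paste(c1, c2))
  }
  # a specific 3-codon toy: one synonymous and one nonsynonymous change
  res3 <- nei_gojobori_dnds(c(a = "ATGGCTAAA", b = "ATGGCCAGA"))
  or_d <- oracle_ng_codon_diffs("GCT", "GCC")["sd"] +
    oracle_ng_codon_diffs("AAA", "AGA")["sd"]
  expect_equal(res3$Sd, unname(or_d), tolerance = 1e-12)
})

test_that("neutrally evolved pairs have dN/dS near one", {
  mutate_uniform <- function(s, nsub) {
    b <- strsplit(s, "")[[1]]
    for (p in sample(length(b), nsub))
      b[p] <- sample(setdiff(ORACLE_BASES, b[p]), 1)
    paste(b, collapse = "")
  }
  set.seed(2024)
  ratios <- vapply(1:50, function(i) {
    ref <- make_reference_cds(generator_config(seed = 3000 + i))
    nei_gojobori_dnds(c(a = mutate_uniform(ref, 80),
                        b = mutate_uniform(ref, 80)))$ratio
  }, numeric(1))
  expect_lt(abs(stats::median(ratios) - 1), 0.1)
})

test_that("5' and 3' regions are indistinguishable under neutral evolution", {
  mutate_uniform <- function(s, nsub) {
    b <- strsplit(s, "")[[1]]
    for (p in sample(length(b), nsub))
      b[p] <- sample(setdiff(ORACLE_BASES, b[p]), 1)
    paste(b, collapse = "")
  }
  set.seed(7)
  r5 <- numeric(0); r3 <- numeric(0)
  for (i in 1:30) {
    ref <- make_reference_cds(generator_config(seed = 5000 + i))
    a <- mutate_uniform(ref, 100)
    b <- mutate_uniform(ref, 100)
    res5 <- nei_gojobori_dnds(c(a = a, b = b), region = 1:88)
    res3 <- nei_gojobori_dnds(c(a = a, b = b), region = 169:390)
    if (res5$ratio_defined) r5 <- c(r5, res5$ratio)
    if (res3$ratio_defined) r3 <- c(r3, res3$ratio)
  }
  expect_gt(stats::wilcox.test(r5, r3)$p.value, 0.01)
})

test_that("the chi-square ratio comparison uses the lower-tail F convention", {
  res <- chisq_ratio_test(10.66, 2, 9.59, 2)
  expect_equal(res$F, (10.66 / 2) / (9.59 / 2), tolerance = 1e-12)
  expect_equal(res$F, 1.11, tolerance = 0.005)
  expect_equal(res$p, 0.53, tolerance = 0.01)
  expect_equal(chisq_ratio_test(5, 3, 5, 3)$F, 1)
  expect_equal(chisq_ratio_test(8, 4, 4, 2)$F, 1)
  expect_error(chisq_ratio_test(0, 2, 1, 2), "positive")
})
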