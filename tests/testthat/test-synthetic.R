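test_that("the reference CDS satisfies its construction contract", {
  cfg <- generator_config(seed = 4)
  ref <- make_reference_cds(cfg)
  expect_equal(nchar(ref), 1173)
  expect_identical(substr(ref, 1, 3), "ATG")
  codons <- substring(ref, seq(1, 1171, 3), seq(3, 1173, 3))
  aas <- Biostrings::GENETIC_CODE[codons]
  expect_equal(sum(aas == "*"), 1)
  expect_equal(unname(which(aas == "*")), 391)
  # determinism under the seed
  expect_identical(ref, make_reference_cds(generator_config(seed = 4)))
  expect_false(identical(ref, make_reference_cds(generator_config(seed = 5))))
  expect_error(generator_config(seed = 1, ref_length = 100), "divisible by 3")
  expect_error(generator_config(ref_length = 1173), "seed")
})

test_that("the fixture family carries the documented event structure", {
  fam <- rtg_family_fixture(generator_config(seed = 1))
  expect_length(fam$copies, 21)
  expect_setequal(names(fam$copies), c("hyrax", "manatee", paste0("RTG", 1:19)))
  has_event <- function(nm, start, len)
    any(fam$events[[nm]]$kind == "deletion" &
          fam$events[[nm]]$ref_start == start & fam$events[[nm]]$length == len)
  # the pre-clade pair is shared by all 21 copies
  expect_true(all(vapply(names(fam$copies), has_event, logical(1),
                         start = 635, len = 1)))
  expect_true(all(vapply(names(fam$copies), has_event, logical(1),
                         start = 671, len = 2)))
  # the 7-bp deletion is absent only from the manatee
  d7 <- vapply(names(fam$copies), has_event, logical(1), start = 728, len = 7)
  expect_false(d7[["manatee"]])
  expect_true(all(d7[setdiff(names(d7), "manatee")]))
  # exactly copies 8-19 carry the del@574 clade marker
  d574 <- vapply(paste0("RTG", 1:19), has_event, logical(1),
                 start = 574, len = 1)
  expect_equal(sum(d574), 12)
  expect_true(all(d574[paste0("RTG", 8:19)]))
  # all elephant copies carry the basal 15-bp and 2-bp deletions
  expect_true(all(vapply(paste0("RTG", 1:19), has_event, logical(1),
                         start = 229, len = 15)))
  expect_true(all(vapply(paste0("RTG", 1:19), has_event, logical(1),
                         start = 487, len = 2)))
  # RTG7 emulates the lost start codon
  expect_false(identical(substr(fam$copies[["RTG7"]], 1, 3), "ATG"))
})

test_that("every fixture copy is reconstructible from its event log", {
  fam <- rtg_family_fixture(generator_config(seed = 2))
  for (nm in names(fam$copies)) {
    mut <- strsplit(fam$reference, "")[[1]]
    s <- fam$substitutions[[nm]]
    if (nrow(s) > 0) mut[s$pos] <- s$base
    expect_identical(apply_events(paste(mut, collapse = ""), fam$events[[nm]]),
                     fam$copies[[nm]], label = nm)
    # alignment rows are the copies, gapped
    expect_identical(gsub("-", "", fam$alignment[[nm]], fixed = TRUE),
                     fam$copies[[nm]])
  }
  # deterministic regeneration
  fam2 <- rtg_family_fixture(generator_config(seed = 2))
  expect_identical(fam2$copies, fam$copies)
})

test_that("fixture substitutions never disturb the truncation arithmetic", {
  fam <- rtg_family_fixture(generator_config(seed = 3))
  scan <- rtg_scan(fam)
  fr <- scan$frame_reports
  eleph <- fr[grepl("^RTG", fr$copy), ]
  expect_true(all(eleph$first_shift_onset %in% c(92, 158)))
  basal <- eleph[!eleph$copy %in% paste0("RTG", 8:19), ]
  expect_equal(basal$matched, rep(157, nrow(basal)))
  expect_equal(fr$matched[fr$copy == "hyrax"], 241 - 12)
})

test_that("a family evolved at zero rates is identical to the reference", {
  cfg <- generator_config(seed = 6, substitution_rate = 0, indel_rate = 0,
                          ref_length = 300)
  g <- simulate_genealogy(drift_params(1, 1e-6), 5, seed = 8,
                          horizon_generations = 4e6)
  fam <- evolve_family(cfg, g)
  expect_true(all(vapply(fam$copies, identical, logical(1), fam$reference)))
  expect_true(all(vapply(fam$events, nrow, integer(1)) == 0))
})

test_that("substitution counts follow the Poisson expectation along the tree", {
  rate <- 2e-7
  counts <- unlist(lapply(1:8, function(i) {
    cfg <- generator_config(seed = 40 + i, substitution_rate = rate,
                            ref_length = 600)
    g <- simulate_genealogy(drift_params(1, 1e-6), 4, seed = 70 + i)
    fam <- evolve_family(cfg, g)
    depth <- max(ape::node.depth.edgelength(fam$tree))
    expected <- rate * depth * 600
    vapply(fam$substitutions, nrow, integer(1)) / expected
  }))
  # ratios of observed to expected root-to-tip substitutions near 1
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 1), 3 * se + 0.05)
})

test_that("evolved-event logs round-trip through extraction", {
  cfg <- generator_config(seed = 10, substitution_rate = 5e-8,
                          indel_rate = 3e-9, ref_length = 600)
  g <- simulate_genealogy(drift_params(1, 1e-6), 8, seed = 11)
  fam <- evolve_family(cfg, g)
  n_unamb <- 0L; n_exact <- 0L
  for (nm in names(fam$copies)) {
    ex <- suppressWarnings(
      extract_events(fam$alignment[["reference"]], fam$alignment[[nm]]))
    # indel bookkeeping must balance: derived length is reproduced exactly
    del <- ex$events$kind == "deletion"
    expect_equal(nchar(fam$copies[[nm]]),
                 600 - sum(ex$events$length[del]) +
                   sum(ex$events$length[!del]))
    tru <- fam$events[[nm]]
    key <- function(e) paste(e$kind, e$ref_start, e$length, sep = ":")
    unamb <- is.na(ex$events$amb_start)
    n_unamb <- n_unamb + sum(unamb)
    n_exact <- n_exact + sum(key(ex$events[unamb, ]) %in% key(tru))
  }
  if (n_unamb > 0) expect_gte(n_exact / n_unamb, 0.95)
})

test_that("bundles write, regenerate byte-identically, and record the seed", {
  cfg <- generator_config(seed = 12)
  fam <- rtg_family_fixture(cfg)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p1 <- write_bundle(fam, dir1)
  expect_true(all(file.exists(p1)))
  m <- jsonlite::read_json(p1[["manifest"]])
  expect_equal(m$config$seed, 12)
  cfg2 <- read_bundle_manifest(p1[["manifest"]])
  p2 <- write_bundle(rtg_family_fixture(cfg2), dir2)
  for (f in c("reference", "copies", "alignment")) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
  # the aligned FASTA round-trips through the scan reader
  aln <- Biostrings::readDNAStringSet(p1[["alignment"]])
  expect_equal(length(aln), 22)
  scan <- rtg_scan(aln, reference_label = "reference")
  expect_equal(nrow(scan$frame_reports), 21)
})
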