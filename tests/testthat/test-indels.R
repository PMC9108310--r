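test_that("apply_events performs the length arithmetic of the printed events", {
  ref <- random_ref(1173, seed = 21)
  expect_identical(apply_events(ref, indel_events()), ref)
  one <- apply_events(ref, indel_events("deletion", 229, 15))
  expect_equal(nchar(one), 1158)
  basal <- apply_events(ref, indel_events(
    rep("deletion", 5), c(229, 487, 635, 671, 728), c(15, 2, 1, 2, 7)))
  expect_equal(nchar(basal), 1173 - 27)
  ins <- apply_events("ATGAAA", indel_events("insertion", 4, 3, "CCC"))
  expect_identical(ins, "ATGCCCAAA")
  tail_ins <- apply_events("ATG", indel_events("insertion", 4, 2, "GG"))
  expect_identical(tail_ins, "ATGGG")
})

test_that("out-of-bounds and overlapping events are rejected with offenders named", {
  ref <- random_ref(100, seed = 3)
  expect_error(apply_events(ref, indel_events("deletion", 95, 10)),
               "out of bounds.*95")
  expect_error(apply_events(ref, indel_events(c("deletion", "deletion"),
                                              c(10, 12), c(5, 3))),
               "overlapping.*12")
})

test_that("event extraction inverts event application", {
  ref <- "ATGAAACCCGGGTTT"
  ev <- indel_events("deletion", 7, 3)
  aln <- events_to_alignment(ref, ev)
  ex <- extract_events(aln["ref"], aln["copy"])
  expect_equal(ex$events$kind, "deletion")
  expect_equal(ex$events$length, 3L)
  expect_length(ex$substitutions, 0)
  # random references and event sets: reconstruction is exact every time,
  # and unambiguous events round-trip identically
  for (i in 1:25) {
    ref <- random_ref(300, seed = 400 + i)
    set.seed(500 + i)
    starts <- sort(sample(seq(10, 250, by = 40), 3))
    lens <- sample(1:6, 3, replace = TRUE)
    kinds <- sample(c("deletion", "insertion"), 3, replace = TRUE)
    seqs <- ifelse(kinds == "insertion",
                   vapply(lens, function(l) random_ref(l, 600 + i + l),
                          character(1)), NA)
    ev <- indel_events(kinds, starts, lens, seqs)
    copy <- apply_events(ref, ev)
    aln <- events_to_alignment(ref, ev)
    ex <- extract_events(aln["ref"], aln["copy"])
    expect_identical(apply_events(ref, ex$events), copy)
    unamb <- is.na(ex$events$amb_start)
    if (any(unamb)) {
      got <- paste(ex$events$kind, ex$events$ref_start,
                   ex$events$length)[unamb]
      truth <- paste(ev$kind, ev$ref_start, ev$length)
      expect_true(all(got %in% truth),
                  info = paste(setdiff(got, truth), collapse = "; "))
    }
  }
})

test_that("deletions in repeats are left-normalized with the ambiguity recorded", {
  # homopolymer emulating the ambiguous 1-bp deletion around ref bp 291-294
  ref <- paste0(random_ref(290, seed = 8), "AAAA", random_ref(20, seed = 9))
  substr(ref, 290, 290) <- "C"            # ensure base 290 bounds the run
  run <- oracle_equivalent_deletions(ref, 292, 1)
  for (s in run) {
    ev <- indel_events("deletion", s, 1)
    aln <- events_to_alignment(ref, ev)
    ex <- extract_events(aln["ref"], aln["copy"])
    expect_equal(ex$events$ref_start, min(run))
    expect_equal(ex$events$amb_start, min(run))
    expect_equal(ex$events$amb_end, max(run))
  }
  # a deletion with no repeat context is reported as unique
  expect_length(oracle_equivalent_deletions("ATGCATGCAT", 4, 1), 1)
  ex2 <- extract_events("ATGCATGCAT", "ATG-ATGCAT")
  expect_true(is.na(ex2$events$amb_start))
})

test_that("columns gapped in both sequences are dropped with a warning", {
  expect_warning(ex <- extract_events("AT-GC", "AT-G-"), "gapped in both")
  expect_equal(ex$events$kind, "deletion")
  expect_equal(ex$events$ref_start, 4L)
  expect_error(extract_events("ATG", "ATGC"), "equal length")
})

test_that("event tables round-trip through TSV", {
  ev <- indel_events(c("deletion", "insertion"), c(10, 20), c(3, 2),
                     c(NA, "GT"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_events(ev, f)
  back <- read_events(f)
  expect_equal(back$kind, ev$kind)
  expect_equal(back$ref_start, ev$ref_start)
  expect_equal(back$length, ev$length)
  expect_equal(back$inserted_seq, ev$inserted_seq)
})
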