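#' Synthetic retrogene family generator
#'
#' Generates every input the analysis pipeline needs without external
#' downloads: a canonical CDS emulating the 1173-bp elephant TP53 coding
#' sequence, a deterministic fixture family carrying the indel configuration
#' reported for the African elephant TP53 retrogene family, stochastic
#' families evolved along simulated duplication genealogies, and
#' copy-number trajectories.
#'
#' @name synthetic-data
#' @keywords internal
NULL

#' Generator configuration
#'
#' @param ref_length Reference CDS length in bases (divisible by 3; default
#'   1173 = 390 codons + stop).
#' @param gc_fraction GC content of random bases (default 0.5).
#' @param substitution_rate Substitutions per site per branch-length unit
#'   for [evolve_family()] (default 1e-8, with branch lengths in
#'   generations).
#' @param indel_rate Indels per site per branch-length unit for
#'   [evolve_family()] (default 0).
#' @param indel_length_mean Mean indel length in bases (geometric; default 2).
#' @param fixture_divergence Cumulative per-site substitution probability
#'   applied independently to each fixture copy (default 0.05, low enough
#'   that the printed coordinate arithmetic is never disturbed).
#' @param seed Integer seed (mandatory: every generator path is
#'   deterministic given the seed).
#' @param canonical_protein_length Canonical protein length in amino acids
#'   (default `ref_length/3 - 1`).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(ref_length = 1173L, gc_fraction = 0.5,
                             substitution_rate = 1e-8, indel_rate = 0,
                             indel_length_mean = 2, fixture_divergence = 0.05,
                             seed, canonical_protein_length = NULL) {
  if (missing(seed) || !is.numeric(seed))
    stop("an integer seed is mandatory", call. = FALSE)
  if (ref_length %% 3L != 0L)
    stop("ref_length must be divisible by 3", call. = FALSE)
  if (ref_length < 6L) stop("ref_length must be at least 6", call. = FALSE)
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("gc_fraction must lie in (0, 1)", call. = FALSE)
  if (substitution_rate < 0 || indel_rate < 0 || fixture_divergence < 0)
    stop("rates must be non-negative", call. = FALSE)
  if (is.null(canonical_protein_length))
    canonical_protein_length <- ref_length %/% 3L - 1L
  structure(list(ref_length = as.integer(ref_length),
                 gc_fraction = gc_fraction,
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 indel_length_mean = indel_length_mean,
                 fixture_divergence = fixture_divergence,
                 seed = as.integer(seed),
                 canonical_protein_length = as.integer(canonical_protein_length)),
            class = "generator_config")
}

.rand_base <- function(n, gc) {
  sample(.BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

.rand_sense_codon <- function(gc) {
  repeat {
    cd <- paste(.rand_base(3L, gc), collapse = "")
    if (!.is_stop(cd)) return(cd)
  }
}

# Fixture geometry (reference coordinates) used when ref_length is 1173.
# - bp 290..295 = C AAAA G: homopolymer making a 1-bp deletion at 291
#   ambiguous across 291-294;
# - bp 519-521 = TAA, a stop read in the frame shifted by the basal 17 bp of
#   deletions (derived codon 168 after del15@229 + del2@487);
# - bp 1016-1018 = TAA and 1022-1024 = TGA, the stop pair read in the frame
#   shifted by the net 10-bp pre-clade deletions;
# - the 12-codon scrambled window between del1@635 and del2@671 is kept
#   stop-free in the shifted frame.
.FIXTURE_CODONS <- list(`97` = "GCA", `98` = "AAA", `99` = "GGT",
                        `173` = "GGT", `174` = "AAG",
                        `339` = "CTA", `340` = "ACC", `341` = "CTG",
                        `342` = "AGT")

# Triplets read in the shifted frame between del1@635 and del2@671
# (derived codons 212-223 of the pre-clade copy), as reference positions.
.SCRAMBLED_WINDOW_TRIPLETS <- c(list(c(634L, 636L, 637L)),
                                lapply(seq(638L, 668L, by = 3L),
                                       function(s) s + 0:2))

#' Generate the canonical reference CDS
#'
#' Builds a random coding sequence: an ATG start, random sense codons, and a
#' single terminal stop codon, with no internal in-frame stops. At the
#' default length of 1173 bp, sequence features needed by the deterministic
#' fixture are embedded: a homopolymer context around bp 291-294, stop
#' codons in the shifted reading frames at bp 519-521 and bp 1016-1024 (the
#' frames produced by the fixture's frameshifting deletions), and a
#' stop-free shifted-frame window between bp 635 and 671.
#'
#' @param config A [generator_config()].
#' @return The reference CDS as a character string.
#' @export
make_reference_cds <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old <- .save_rng(config$seed)
  on.exit(.restore_rng(old))
  n_codons <- config$ref_length %/% 3L
  codons <- c("ATG",
              vapply(seq_len(n_codons - 2L), function(i)
                .rand_sense_codon(config$gc_fraction), character(1)),
              "TAA")
  if (config$ref_length == 1173L) {
    for (nm in names(.FIXTURE_CODONS))
      codons[as.integer(nm)] <- .FIXTURE_CODONS[[nm]]
    # keep the shifted-frame scrambled window stop-free
    repeat {
      ref <- paste(codons, collapse = "")
      bad <- vapply(.SCRAMBLED_WINDOW_TRIPLETS, function(tp)
        .is_stop(paste(substring(ref, tp, tp), collapse = "")), logical(1))
      if (!any(bad)) break
      tp <- .SCRAMBLED_WINDOW_TRIPLETS[[which(bad)[1L]]]
      ci <- (tp[2L] - 1L) %/% 3L + 1L    # canonical codon holding the middle
      codons[ci] <- .rand_sense_codon(config$gc_fraction)
    }
  }
  paste(codons, collapse = "")
}

# Per-copy indel configuration of the deterministic fixture family, in
# reference coordinates. The length-3 deletion at 882 is mechanically a
# deletion in every copy but records the 3-bp insertion gained by the
# reference lineage (absent from all retrogenes and outgroup copies).
.fixture_event_sets <- function() {
  shared_all <- list(c("deletion", 635L, 1L), c("deletion", 671L, 2L),
                     c("deletion", 882L, 3L))
  del7 <- list(c("deletion", 728L, 7L))
  eleph_basal <- list(c("deletion", 229L, 15L), c("deletion", 487L, 2L))
  sets <- list(manatee = shared_all, hyrax = c(shared_all, del7))
  for (i in 1:19) {
    ev <- c(shared_all, del7, eleph_basal)
    if (i >= 8L) ev <- c(ev, list(c("deletion", 291L, 1L),
                                  c("deletion", 574L, 1L)))
    if (i >= 2L && i <= 5L) ev <- c(ev, list(c("deletion", 597L, 1L)))
    if (i >= 3L && i <= 5L) ev <- c(ev, list(c("deletion", 813L, 1L)))
    sets[[paste0("RTG", i)]] <- ev
  }
  lapply(sets, function(s) {
    m <- do.call(rbind, s)
    indel_events(kind = m[, 1L], ref_start = as.integer(m[, 2L]),
                 length = as.integer(m[, 3L]))
  })
}

# Reference positions that fixture substitutions must not touch: the start
# codon, the engineered homopolymer and stop contexts, the stop-free
# scrambled window, and the terminal stop.
.fixture_protected <- function(ref_length) {
  unique(c(1:3, 289:297, 517:522, 634:672, 1015:1026,
           (ref_length - 2L):ref_length))
}

# TRUE if substituting position p of `bases` with `b` creates a stop triplet
# in any of the three reading frames (checked over the local window).
.creates_stop <- function(bases, p, b) {
  old <- bases[p]
  bases[p] <- b
  L <- base::length(bases)
  for (s in max(1L, p - 2L):p) {
    if (s + 2L > L) next
    if (.is_stop(paste(bases[s:(s + 2L)], collapse = ""))) {
      bases[p] <- old
      return(TRUE)
    }
  }
  bases[p] <- old
  FALSE
}

#' Deterministic fixture family with the published indel configuration
#'
#' Builds the 21-copy family (19 elephant retrogenes, one hyrax and one
#' manatee outgroup copy) by applying the documented deletion sets to the
#' synthetic reference: all copies share del1@635 and del2@671-672 (and lack
#' the reference's 3-bp insertion at 882-884); hyrax and all elephant copies
#' add del7@728-734; all elephant copies add del15@229-243 and del2@487-488;
#' copies 8-19 add del1@291 and del1@574; copies 2-5 add del1@597; copies
#' 3-5 add del1@813. Background substitutions are applied to each copy at
#' `fixture_divergence` per site, avoiding positions and changes that would
#' disturb the engineered truncation arithmetic (no new stop codons in any
#' local reading frame, protected windows untouched). Copy RTG7's start
#' codon is substituted to GTG, emulating the reported start-codon loss.
#'
#' @param config A [generator_config()] with the default `ref_length` 1173.
#' @return A list of class `family_bundle`: `reference`, `copies`,
#'   `events` (per-copy [indel_events()]), `substitutions` (per-copy data
#'   frames of `pos`, `base`), `alignment` (named gapped sequences including
#'   `reference`), `tree` ([ape::phylo]), `config`, `notes`.
#' @examples
#' fam <- rtg_family_fixture(generator_config(seed = 1))
#' names(fam$copies)[1:4]
#' @export
rtg_family_fixture <- function(config = generator_config(seed = 20220425L)) {
  stopifnot(inherits(config, "generator_config"))
  if (config$ref_length != 1173L)
    stop("the fixture family requires the default 1173-bp reference",
         call. = FALSE)
  ref <- make_reference_cds(config)
  sets <- .fixture_event_sets()
  old <- .save_rng(config$seed + 1L)
  on.exit(.restore_rng(old))
  ref_bases <- strsplit(ref, "", fixed = TRUE)[[1]]
  protected <- .fixture_protected(config$ref_length)
  copies <- character(0); subs <- list()
  for (nm in names(sets)) {
    ev <- sets[[nm]]
    deleted <- unlist(mapply(function(s, l) s:(s + l - 1L),
                             ev$ref_start[ev$kind == "deletion"],
                             ev$length[ev$kind == "deletion"],
                             SIMPLIFY = FALSE))
    eligible <- setdiff(seq_len(config$ref_length), union(protected, deleted))
    n_sub <- stats::rbinom(1L, base::length(eligible),
                           config$fixture_divergence)
    pos <- sort(sample(eligible, n_sub))
    mut <- ref_bases
    kept_pos <- integer(0); kept_base <- character(0)
    for (p in pos) {
      for (b in sample(setdiff(.BASES, mut[p]))) {
        if (!.creates_stop(mut, p, b)) {
          mut[p] <- b
          kept_pos <- c(kept_pos, p); kept_base <- c(kept_base, b)
          break
        }
      }
    }
    if (nm == "RTG7" && !1L %in% kept_pos) {   # emulate the lost ATG start
      mut[1L] <- "G"
      kept_pos <- c(1L, kept_pos); kept_base <- c("G", kept_base)
    }
    subs[[nm]] <- data.frame(pos = kept_pos, base = kept_base)
    copies[[nm]] <- apply_events(paste(mut, collapse = ""), ev)
  }
  aln <- .alignment_from_logs(ref, sets, subs)
  tree_txt <- paste0("(manatee,(hyrax,(RTG1,RTG6,RTG7,",
                     "(RTG2,(RTG3,RTG4,RTG5)),",
                     "(", paste(paste0("RTG", 8:19), collapse = ","), "))));")
  structure(list(reference = ref, copies = copies, events = sets,
                 substitutions = subs, alignment = aln,
                 tree = ape::read.tree(text = tree_txt), config = config,
                 notes = paste("del3@882 in every copy records the 3-bp",
                               "insertion gained by the reference lineage;",
                               "the reported 25-bp and 5-bp insertions are",
                               "not coordinate-localized and are omitted")),
            class = "family_bundle")
}

# Build a gapped alignment from per-copy event logs and substitutions.
# Columns are the reference positions plus one block per unique insertion
# event (keyed by anchor and sequence), so correctness is by construction.
.alignment_from_logs <- function(ref, event_sets, subs) {
  L <- nchar(ref)
  ref_bases <- strsplit(ref, "", fixed = TRUE)[[1]]
  ins_keys <- character(0)
  for (nm in names(event_sets)) {
    ev <- event_sets[[nm]]
    ins <- ev[ev$kind == "insertion", , drop = FALSE]
    if (nrow(ins) > 0L)
      ins_keys <- union(ins_keys, paste(ins$ref_start, ins$inserted_seq,
                                        sep = ":"))
  }
  ins_tab <- NULL
  if (base::length(ins_keys) > 0L) {
    parts <- strsplit(ins_keys, ":", fixed = TRUE)
    ins_tab <- data.frame(anchor = as.integer(vapply(parts, `[`, "", 1L)),
                          seq = vapply(parts, `[`, "", 2L))
    ins_tab <- ins_tab[order(ins_tab$anchor, ins_tab$seq), , drop = FALSE]
  }
  build_row <- function(bases, ev) {
    del <- rep(FALSE, L)
    if (!is.null(ev)) {
      d <- ev[ev$kind == "deletion", , drop = FALSE]
      for (i in seq_len(nrow(d)))
        del[d$ref_start[i]:(d$ref_start[i] + d$length[i] - 1L)] <- TRUE
    }
    has_ins <- function(anchor, seq) {
      !is.null(ev) && any(ev$kind == "insertion" & ev$ref_start == anchor &
                            ev$inserted_seq == seq)
    }
    out <- character(0)
    for (p in seq_len(L + 1L)) {
      if (!is.null(ins_tab)) {
        blk <- ins_tab[ins_tab$anchor == p, , drop = FALSE]
        for (i in seq_len(nrow(blk)))
          out <- c(out, if (has_ins(blk$anchor[i], blk$seq[i])) blk$seq[i]
                   else strrep("-", nchar(blk$seq[i])))
      }
      if (p <= L) out <- c(out, if (del[p]) "-" else bases[p])
    }
    paste(out, collapse = "")
  }
  aln <- c(reference = build_row(ref_bases, NULL))
  for (nm in names(event_sets)) {
    bases <- ref_bases
    sb <- subs[[nm]]
    if (!is.null(sb) && nrow(sb) > 0L) bases[sb$pos] <- sb$base
    aln[[nm]] <- build_row(bases, event_sets[[nm]])
  }
  aln
}

#' Evolve a stochastic retrogene family along a genealogy
#'
#' The stochastic counterpart of [rtg_family_fixture()] for property tests:
#' the reference evolves down the duplication genealogy with independent
#' uniform substitutions (no selection) and optional indels; every tip's
#' true event log and substitution set is returned, and each derived copy
#' satisfies `apply_events(substituted reference, log) == copy`.
#'
#' Indels are drawn with geometric lengths (mean `indel_length_mean`);
#' deletions take contiguous reference ranges not previously deleted on the
#' lineage, insertions anchor before a surviving reference position, and
#' nested insertions are not modeled.
#'
#' @param config A [generator_config()].
#' @param genealogy A `duplication_genealogy` from [simulate_genealogy()],
#'   or an [ape::phylo] tree with branch lengths in the units of
#'   `substitution_rate`.
#' @return A `family_bundle` (see [rtg_family_fixture()]).
#' @export
evolve_family <- function(config, genealogy) {
  stopifnot(inherits(config, "generator_config"))
  tree <- if (inherits(genealogy, "duplication_genealogy")) genealogy$tree
  else genealogy
  ref <- make_reference_cds(config)
  L <- config$ref_length
  old <- .save_rng(config$seed + 2L)
  on.exit(.restore_rng(old))
  if (is.null(tree)) {            # single-copy genealogy
    nm <- "RTG1"
    sets <- stats::setNames(list(indel_events()), nm)
    subs <- stats::setNames(list(data.frame(pos = integer(0),
                                            base = character(0))), nm)
    copies <- stats::setNames(ref, nm)
    aln <- .alignment_from_logs(ref, sets, subs)
    return(structure(list(reference = ref, copies = copies, events = sets,
                          substitutions = subs, alignment = aln, tree = NULL,
                          config = config, notes = "single-copy family"),
                     class = "family_bundle"))
  }
  stopifnot(inherits(tree, "phylo"))
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- base::length(tree$tip.label)
  root <- ntip + 1L
  ins_counter <- 0L
  empty_state <- list(sub = integer(0),     # named int: pos -> base index
                      del = integer(0),     # deleted ref positions
                      ins = list())         # list of (anchor, seq)
  states <- vector("list", ntip + tree$Nnode)
  states[[root]] <- empty_state
  mean_div <- 0
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]; chl <- tree$edge[e, 2L]
    st <- states[[par]]
    len <- tree$edge.length[e]
    alive <- setdiff(seq_len(L), st$del)
    n_sub <- stats::rpois(1L, config$substitution_rate * len *
                            base::length(alive))
    if (n_sub > 0L) {
      pos <- sample(alive, min(n_sub, base::length(alive)))
      for (p in pos) {
        cur <- if (as.character(p) %in% names(st$sub))
          .BASES[st$sub[[as.character(p)]]] else substr(ref, p, p)
        st$sub[[as.character(p)]] <- match(sample(setdiff(.BASES, cur), 1L),
                                           .BASES)
      }
    }
    n_ind <- stats::rpois(1L, config$indel_rate * len * base::length(alive))
    for (ii in seq_len(n_ind)) {
      ilen <- 1L + stats::rgeom(1L, 1 / config$indel_length_mean)
      if (stats::runif(1L) < 0.5) {          # deletion
        for (try in 1:20) {
          s <- sample(alive, 1L)
          rng <- s:(min(s + ilen - 1L, L))
          if (base::length(rng) == ilen && !any(rng %in% st$del)) {
            st$del <- c(st$del, rng)
            alive <- setdiff(alive, rng)
            break
          }
        }
      } else {                               # insertion
        anchors_used <- vapply(st$ins, `[[`, 0L, "anchor")
        avail <- setdiff(alive, anchors_used)
        if (base::length(avail) > 0L) {
          a <- sample(avail, 1L)
          ins_counter <- ins_counter + 1L
          st$ins[[base::length(st$ins) + 1L]] <-
            list(anchor = a,
                 seq = paste(.rand_base(ilen, config$gc_fraction),
                             collapse = ""))
        }
      }
    }
    states[[chl]] <- st
  }
  sets <- list(); subs <- list(); copies <- character(0)
  ref_bases <- strsplit(ref, "", fixed = TRUE)[[1]]
  for (t in seq_len(ntip)) {
    nm <- tree$tip.label[t]
    st <- states[[t]]
    # contiguous runs of deleted positions -> deletion events
    kinds <- character(0); starts <- integer(0); lens <- integer(0)
    seqs <- character(0)
    if (base::length(st$del) > 0L) {
      d <- sort(unique(st$del))
      runs <- split(d, cumsum(c(1L, diff(d) != 1L)))
      for (r in runs) {
        kinds <- c(kinds, "deletion"); starts <- c(starts, r[1L])
        lens <- c(lens, base::length(r)); seqs <- c(seqs, NA_character_)
      }
    }
    for (iv in st$ins) {
      kinds <- c(kinds, "insertion"); starts <- c(starts, iv$anchor)
      lens <- c(lens, nchar(iv$seq)); seqs <- c(seqs, iv$seq)
    }
    ev <- indel_events(kinds, starts, lens, seqs)
    sub_pos <- as.integer(names(st$sub))
    sub_base <- .BASES[unlist(st$sub)]
    # drop substitutions landing on deleted positions (invisible in copy)
    keep <- !sub_pos %in% st$del
    sdf <- data.frame(pos = sub_pos[keep], base = sub_base[keep])
    sdf <- sdf[order(sdf$pos), , drop = FALSE]
    mut <- ref_bases
    if (nrow(sdf) > 0L) mut[sdf$pos] <- sdf$base
    sets[[nm]] <- ev
    subs[[nm]] <- sdf
    copies[[nm]] <- apply_events(paste(mut, collapse = ""), ev)
    mean_div <- mean_div + nrow(sdf) / L / ntip
  }
  if (mean_div > 0.5)
    warning("mean divergence exceeds 50% of sites; rates may be too high",
            call. = FALSE)
  aln <- .alignment_from_logs(ref, sets, subs)
  structure(list(reference = ref, copies = copies, events = sets,
                 substitutions = subs, alignment = aln, tree = tree,
                 config = config, notes = "stochastic family"),
            class = "family_bundle")
}

#' Write a family bundle to disk
#'
#' Emits `reference.fasta`, `copies.fasta`, `alignment.fasta`,
#' `genealogy.nwk` (when a tree is present), `events.tsv`,
#' `substitutions.tsv` and `manifest.json`. The manifest records the full
#' generator configuration including the seed, so the bundle can be
#' regenerated byte-identically.
#'
#' @param bundle A `family_bundle`.
#' @param directory Output directory (created if needed).
#' @return Invisibly, the named vector of written file paths.
#' @export
write_bundle <- function(bundle, directory) {
  stopifnot(inherits(bundle, "family_bundle"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(reference = file.path(directory, "reference.fasta"),
             copies = file.path(directory, "copies.fasta"),
             alignment = file.path(directory, "alignment.fasta"),
             events = file.path(directory, "events.tsv"),
             substitutions = file.path(directory, "substitutions.tsv"),
             manifest = file.path(directory, "manifest.json"))
  wr <- function(x, p) {
    res <- try(Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(x), p), silent = TRUE)
    if (inherits(res, "try-error"))
      stop("failed to write ", p, ": ", attr(res, "condition")$message,
           call. = FALSE)
  }
  wr(c(reference = bundle$reference), paths["reference"])
  wr(bundle$copies, paths["copies"])
  wr(bundle$alignment, paths["alignment"])
  if (!is.null(bundle$tree)) {
    paths <- c(paths, genealogy = file.path(directory, "genealogy.nwk"))
    ape::write.tree(bundle$tree, paths["genealogy"])
  }
  ev_all <- do.call(rbind, lapply(names(bundle$events), function(nm) {
    ev <- as.data.frame(bundle$events[[nm]])
    if (nrow(ev) == 0L) NULL else cbind(copy = nm, ev)
  }))
  if (is.null(ev_all))
    ev_all <- cbind(copy = character(0), as.data.frame(indel_events()))
  utils::write.table(ev_all, paths["events"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  sub_all <- do.call(rbind, lapply(names(bundle$substitutions), function(nm) {
    s <- bundle$substitutions[[nm]]
    if (nrow(s) == 0L) NULL else cbind(copy = nm, s)
  }))
  if (is.null(sub_all))
    sub_all <- data.frame(copy = character(0), pos = integer(0),
                          base = character(0))
  utils::write.table(sub_all, paths["substitutions"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(generator = "retrodrift",
                   version = as.character(utils::packageVersion("retrodrift")),
                   config = unclass(bundle$config),
                   n_copies = base::length(bundle$copies),
                   notes = bundle$notes)
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Read a bundle manifest back into a generator configuration
#'
#' @param path Path to a `manifest.json` written by [write_bundle()].
#' @return The [generator_config()] recorded in the manifest.
#' @export
read_bundle_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- m$config
  generator_config(ref_length = cfg$ref_length, gc_fraction = cfg$gc_fraction,
                   substitution_rate = cfg$substitution_rate,
                   indel_rate = cfg$indel_rate,
                   indel_length_mean = cfg$indel_length_mean,
                   fixture_divergence = cfg$fixture_divergence,
                   seed = cfg$seed,
                   canonical_protein_length = cfg$canonical_protein_length)
}
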