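#' Track reading-frame segments through an indel history
#'
#' Walks the derived sequence implied by an event list and partitions its
#' codons into segments of constant frame offset. The frame offset is the
#' net upstream indel length modulo 3 (0 = in frame); a segment boundary
#' occurs at every event that changes the offset, at the product codon
#' containing the event's derived-coordinate position.
#'
#' @param events An [indel_events()] data frame in reference coordinates.
#' @param ref_length Length of the reference CDS in bases.
#' @return A data frame of class `frame_segments` with columns `start_codon`,
#'   `end_codon` (1-based product codons, inclusive), `frame_offset` (0/1/2)
#'   and `status` (`"in-frame"` or `"scrambled"`). Attribute `derived_length`
#'   records the derived sequence length.
#' @examples
#' ev <- indel_events(c("deletion", "deletion"), c(229, 487), c(15, 2))
#' frame_track(ev, 1173)  # scrambled from product codon 158
#' @export
frame_track <- function(events, ref_length) {
  .validate_events(events, ref_length)
  del <- events$kind == "deletion"
  derived_length <- ref_length - sum(events$length[del]) +
    sum(events$length[!del])
  n_codons <- as.integer(ceiling(derived_length / 3))
  # boundaries: (codon, offset_after)
  shift <- 0L                          # net indel sum (ins +, del -)
  bnd_codon <- integer(0); bnd_offset <- integer(0)
  if (nrow(events) > 0L) for (i in seq_len(nrow(events))) {
    delta <- if (events$kind[i] == "deletion") -events$length[i] else
      events$length[i]
    new_shift <- shift + delta
    if (new_shift %% 3L != shift %% 3L) {
      derived_pos <- events$ref_start[i] + shift   # first base at/after event
      codon <- (derived_pos - 1L) %/% 3L + 1L
      bnd_codon <- c(bnd_codon, codon)
      bnd_offset <- c(bnd_offset, as.integer(new_shift %% 3L))
    }
    shift <- new_shift
  }
  starts <- c(1L, bnd_codon)
  offsets <- c(0L, bnd_offset)
  ends <- c(bnd_codon - 1L, n_codons)
  keep <- starts <= ends
  # when consecutive boundaries share a codon, the last offset wins
  if (any(!keep)) {
    drop <- which(!keep)
    for (d in rev(drop)) offsets[d + 1L] <- offsets[d + 1L]  # later one stands
    starts <- starts[keep]; ends <- ends[keep]; offsets <- offsets[keep]
  }
  # merge adjacent segments with equal offset
  if (base::length(starts) > 1L) {
    m <- c(TRUE, offsets[-1L] != offsets[-base::length(offsets)])
    grp <- cumsum(m)
    starts <- tapply(starts, grp, min)
    ends <- tapply(ends, grp, max)
    offsets <- offsets[m]
  }
  seg <- data.frame(start_codon = as.integer(starts),
                    end_codon = as.integer(ends),
                    frame_offset = as.integer(offsets),
                    status = ifelse(offsets == 0L, "in-frame", "scrambled"))
  rownames(seg) <- NULL
  attr(seg, "derived_length") <- as.integer(derived_length)
  class(seg) <- c("frame_segments", class(seg))
  seg
}

# Translate one codon under the standard nuclear code; "*" for stops, "X"
# for codons with ambiguous bases.
.codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  ifelse(is.na(aa), "X", aa)
}

#' Per-copy open-reading-frame decay report
#'
#' Translates a derived retrogene copy through its frame segments and
#' summarizes how much of the canonical protein it still encodes. Codons are
#' consumed segment by segment; a stop codon anywhere terminates
#' translation. A scrambled (shifted-frame) segment whose stop terminates
#' translation before the frame is restored is an *unrestored* shift: the
#' canonical-matching count is frozen at the in-frame codons read before its
#' onset. A scrambled segment traversed without a stop contributes its
#' codons to the scrambled tally and translation continues in the restored
#' frame. A terminal scrambled segment is unrestored by construction.
#'
#' @param ref_cds The canonical reference CDS.
#' @param derived The derived copy (ungapped; consistent with `segments`).
#' @param segments A `frame_segments` object from [frame_track()].
#' @param canonical_protein_length Length of the canonical protein in amino
#'   acids (default 390).
#' @return A list of class `frame_report`: `first_shift_onset_codon`,
#'   `unrestored_onset_codon`, `first_stop_codon`, `matched_canonical_codons`,
#'   `scrambled_codons`, `deleted_codons`, `fraction_canonical`, `has_start`,
#'   `terminated`.
#' @export
orf_report <- function(ref_cds, derived, segments,
                       canonical_protein_length = 390L) {
  derived <- .as_seq(derived)
  if (nchar(derived) < 3L)
    stop("derived sequence shorter than one codon", call. = FALSE)
  dl <- attr(segments, "derived_length", exact = TRUE)
  if (!is.null(dl) && dl != nchar(derived))
    stop("derived sequence length (", nchar(derived),
         ") does not match segments (", dl, ")", call. = FALSE)
  ref <- .as_seq(ref_cds)
  n_codons <- nchar(derived) %/% 3L
  codons <- substring(derived, 3L * seq_len(n_codons) - 2L,
                      3L * seq_len(n_codons))
  aas <- .codon_aa(codons)
  has_start <- identical(codons[1L], "ATG")
  matched <- 0L; scrambled <- 0L
  first_shift <- NA_integer_; unrestored <- NA_integer_
  first_stop <- NA_integer_; terminated <- FALSE
  for (i in seq_len(nrow(segments))) {
    span <- segments$start_codon[i]:min(segments$end_codon[i], n_codons)
    if (segments$start_codon[i] > n_codons) break
    if (segments$status[i] == "scrambled" && is.na(first_shift))
      first_shift <- segments$start_codon[i]
    stop_at <- span[which(aas[span] == "*")[1L]]
    if (segments$status[i] == "in-frame") {
      if (!is.na(stop_at)) {
        matched <- matched + sum(span < stop_at)
        first_stop <- stop_at
        terminated <- TRUE
        break
      }
      matched <- matched + base::length(span)
    } else {
      if (!is.na(stop_at)) {                 # unrestored: stop before rescue
        unrestored <- segments$start_codon[i]
        scrambled <- scrambled + sum(span < stop_at)
        first_stop <- stop_at
        terminated <- TRUE
        break
      }
      if (i == nrow(segments)) {             # runs to the end: unrestored
        unrestored <- segments$start_codon[i]
        scrambled <- scrambled + base::length(span)
      } else {
        scrambled <- scrambled + base::length(span)
      }
    }
  }
  deleted <- 0L
  # codons of the canonical protein wholly absent from the product
  total_del <- (nchar(ref) - nchar(derived))
  if (total_del > 0L) deleted <- total_del %/% 3L
  frac <- matched / canonical_protein_length
  structure(list(first_shift_onset_codon = first_shift,
                 unrestored_onset_codon = unrestored,
                 first_stop_codon = first_stop,
                 matched_canonical_codons = matched,
                 scrambled_codons = scrambled,
                 deleted_codons = deleted,
                 fraction_canonical = frac,
                 has_start = has_start,
                 terminated = terminated,
                 canonical_protein_length = as.integer(canonical_protein_length)),
            class = "frame_report")
}

#' @export
print.frame_report <- function(x, ...) {
  cat(sprintf(paste0("<frame_report> matched %d/%d canonical codons (%.1f%%), ",
                     "%d scrambled; shift onset %s, unrestored %s, stop %s%s\n"),
              x$matched_canonical_codons, x$canonical_protein_length,
              100 * x$fraction_canonical, x$scrambled_codons,
              ifelse(is.na(x$first_shift_onset_codon), "-", x$first_shift_onset_codon),
              ifelse(is.na(x$unrestored_onset_codon), "-", x$unrestored_onset_codon),
              ifelse(is.na(x$first_stop_codon), "-", x$first_stop_codon),
              if (!x$has_start) "; no ATG start" else ""))
  invisible(x)
}

#' Summarize substitutions and indel events across an aligned family
#'
#' Counts (i) reference columns at which at least one non-reference sequence
#' carries a differing base (gaps and Ns excluded), and (ii) deletion and
#' insertion events pooled across sequences: events with identical kind,
#' position and length (after left-normalization) are counted once, since
#' they descend from a single mutational event.
#'
#' @param alignment Named character vector (or `DNAStringSet`) of equal-length
#'   gapped sequences, including the reference.
#' @param reference_label Name of the reference sequence in `alignment`.
#' @return A list of class `diff_summary`: `substituted_site_count`,
#'   `deletion_event_count`, `insertion_event_count`, and `events` (the
#'   pooled event table with a `copies` count column).
#' @export
diff_summary <- function(alignment, reference_label) {
  if (inherits(alignment, "XStringSet"))
    alignment <- stats::setNames(as.character(alignment), names(alignment))
  if (!reference_label %in% names(alignment))
    stop("reference '", reference_label, "' absent from alignment",
         call. = FALSE)
  ref <- alignment[[reference_label]]
  copies <- alignment[setdiff(names(alignment), reference_label)]
  sub_cols <- integer(0)
  pooled <- list()
  for (nm in names(copies)) {
    ex <- extract_events(ref, copies[[nm]])
    # exclude N positions from the substitution census
    cb <- strsplit(toupper(copies[[nm]]), "", fixed = TRUE)[[1]]
    rb <- strsplit(toupper(ref), "", fixed = TRUE)[[1]]
    ref_pos <- cumsum(rb != "-")
    n_pos <- ref_pos[rb != "-" & cb == "N"]
    sub_cols <- union(sub_cols, setdiff(ex$substitutions, n_pos))
    if (nrow(ex$events) > 0L) {
      keys <- paste(ex$events$kind, ex$events$ref_start, ex$events$length,
                    ifelse(is.na(ex$events$inserted_seq), "",
                           ex$events$inserted_seq), sep = ":")
      for (ki in seq_along(keys)) {
        k <- keys[ki]
        if (is.null(pooled[[k]]))
          pooled[[k]] <- cbind(ex$events[ki, , drop = FALSE], copies = 1L)
        else pooled[[k]]$copies <- pooled[[k]]$copies + 1L
      }
    }
  }
  ev <- if (base::length(pooled) > 0L) do.call(rbind, pooled) else
    cbind(indel_events(), copies = integer(0))
  rownames(ev) <- NULL
  structure(list(substituted_site_count = base::length(sub_cols),
                 deletion_event_count = sum(ev$kind == "deletion"),
                 insertion_event_count = sum(ev$kind == "insertion"),
                 events = ev),
            class = "diff_summary")
}

#' @export
print.diff_summary <- function(x, ...) {
  cat(sprintf("<diff_summary> %d substituted sites, %d deletion and %d insertion events\n",
              x$substituted_site_count, x$deletion_event_count,
              x$insertion_event_count))
  invisible(x)
}
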