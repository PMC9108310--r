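#' Indel event lists
#'
#' Insertions and deletions against a canonical CDS are recorded in 1-based
#' reference coordinates ("ref bp"). A deletion of `length` at `ref_start`
#' removes reference bases `ref_start .. ref_start+length-1`; an insertion
#' places `inserted_seq` immediately before reference position `ref_start`.
#'
#' @param kind Character vector, `"deletion"` or `"insertion"`.
#' @param ref_start 1-based reference start positions.
#' @param length Event lengths in bases (>= 1).
#' @param inserted_seq Inserted bases (insertions only; `NA` for deletions).
#' @param amb_start,amb_end Optional 1-based span of equivalent placements
#'   when the event sits in a repeat context (`NA` when unique).
#' @return A data frame of class `indel_events`, sorted by `ref_start`.
#' @examples
#' indel_events(kind = c("deletion", "deletion"), ref_start = c(635, 671),
#'              length = c(1, 2))
#' @export
indel_events <- function(kind = character(), ref_start = integer(),
                         length = integer(), inserted_seq = NA_character_,
                         amb_start = NA_integer_, amb_end = NA_integer_) {
  n <- base::length(kind)
  if (n == 0L) {
    ev <- data.frame(kind = character(), ref_start = integer(),
                     length = integer(), inserted_seq = character(),
                     amb_start = integer(), amb_end = integer())
    class(ev) <- c("indel_events", class(ev))
    return(ev)
  }
  if (!all(kind %in% c("deletion", "insertion")))
    stop("kind must be 'deletion' or 'insertion'", call. = FALSE)
  ev <- data.frame(kind = kind,
                   ref_start = as.integer(ref_start),
                   length = as.integer(length),
                   inserted_seq = rep_len(toupper(as.character(inserted_seq)), n),
                   amb_start = rep_len(as.integer(amb_start), n),
                   amb_end = rep_len(as.integer(amb_end), n))
  if (any(ev$ref_start < 1)) stop("ref_start must be >= 1", call. = FALSE)
  if (any(ev$length < 1)) stop("length must be >= 1", call. = FALSE)
  ins <- ev$kind == "insertion"
  if (any(ins & (is.na(ev$inserted_seq) | nchar(ev$inserted_seq) != ev$length)))
    stop("inserted_seq must be supplied for insertions and match length",
         call. = FALSE)
  ev$inserted_seq[!ins] <- NA_character_
  ev <- ev[order(ev$ref_start, ev$kind), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("indel_events", class(ev))
  ev
}

# Coerce sequence input (character, DNAString, DNAStringSet element) to a
# single uppercase character string.
.as_seq <- function(x) {
  if (inherits(x, "XString") || inherits(x, "XStringSet"))
    x <- as.character(x)
  if (!is.character(x) || base::length(x) != 1L)
    stop("sequence must be a single character string or DNAString",
         call. = FALSE)
  toupper(x)
}

.validate_events <- function(events, ref_length) {
  if (nrow(events) == 0L) return(invisible(events))
  del <- events[events$kind == "deletion", , drop = FALSE]
  if (nrow(del) > 0L) {
    ends <- del$ref_start + del$length - 1L
    bad <- del$ref_start > ref_length | ends > ref_length
    if (any(bad))
      stop("deletion(s) out of bounds at ref_start ",
           paste(del$ref_start[bad], collapse = ", "), call. = FALSE)
    if (nrow(del) > 1L) {
      o <- order(del$ref_start)
      s <- del$ref_start[o]; e <- ends[o]
      ov <- which(s[-1L] <= e[-base::length(e)])
      if (base::length(ov) > 0L)
        stop("overlapping deletions at ref_start ",
             paste(s[ov + 1L], collapse = ", "), call. = FALSE)
    }
  }
  ins <- events[events$kind == "insertion", , drop = FALSE]
  if (any(ins$ref_start > ref_length + 1L))
    stop("insertion(s) beyond reference end", call. = FALSE)
  invisible(events)
}

#' Apply indel events to a reference sequence
#'
#' Forward construction of a derived copy: deletions remove reference bases,
#' insertions add bases before their anchor position. The derived length is
#' the reference length minus total deleted plus total inserted bases.
#'
#' @param ref_cds Reference CDS (character string or `DNAString`).
#' @param events An [indel_events()] data frame (events in reference
#'   coordinates; deletions must not overlap).
#' @return The derived sequence as a character string.
#' @examples
#' apply_events("ATGAAATTTGGGTAA", indel_events("deletion", 4, 3))
#' @export
apply_events <- function(ref_cds, events) {
  ref <- .as_seq(ref_cds)
  L <- nchar(ref)
  .validate_events(events, L)
  if (nrow(events) == 0L) return(ref)
  keep <- rep(TRUE, L)
  ins_before <- character(L + 1L)   # strings inserted before each position
  for (i in seq_len(nrow(events))) {
    if (events$kind[i] == "deletion") {
      keep[events$ref_start[i]:(events$ref_start[i] + events$length[i] - 1L)] <- FALSE
    } else {
      p <- events$ref_start[i]
      ins_before[p] <- paste0(ins_before[p], events$inserted_seq[i])
    }
  }
  bases <- strsplit(ref, "", fixed = TRUE)[[1]]
  out <- character(0)
  pieces <- vapply(seq_len(L), function(p)
    paste0(ins_before[p], if (keep[p]) bases[p] else ""), character(1))
  paste0(paste(pieces, collapse = ""), ins_before[L + 1L])
}

# Left-normalize a deletion of ref[s..s+len-1] within repeat context.
# Returns list(start, amb_start, amb_end): leftmost equivalent start and the
# reference span covered by all equivalent placements (NA when unique).
.normalize_deletion <- function(ref_bases, s, len) {
  e <- s + len - 1L
  s_left <- s
  while (s_left > 1L && ref_bases[s_left - 1L] == ref_bases[s_left + len - 1L])
    s_left <- s_left - 1L
  s_right <- s
  L <- base::length(ref_bases)
  while (s_right + len - 1L < L && ref_bases[s_right] == ref_bases[s_right + len])
    s_right <- s_right + 1L
  if (s_left == s_right)
    list(start = s_left, amb_start = NA_integer_, amb_end = NA_integer_)
  else
    list(start = s_left, amb_start = s_left,
         amb_end = s_right + len - 1L)
}

# Left-normalize an insertion of `seq` before ref position p: rotate while
# the last inserted base equals the reference base before the anchor.
.normalize_insertion <- function(ref_bases, p, seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  len <- base::length(chars)
  p0 <- p; chars0 <- chars
  while (p > 1L && chars[len] == ref_bases[p - 1L]) {
    chars <- c(ref_bases[p - 1L], chars[-len])
    p <- p - 1L
  }
  # right extent for the ambiguity span
  pr <- p0; chr <- chars0
  L <- base::length(ref_bases)
  while (pr <= L && chr[1L] == ref_bases[pr]) {
    chr <- c(chr[-1L], ref_bases[pr])
    pr <- pr + 1L
  }
  list(start = p, seq = paste(chars, collapse = ""),
       amb_start = if (p == pr) NA_integer_ else p,
       amb_end = if (p == pr) NA_integer_ else pr)
}

#' Extract indel events and substitutions from an aligned pair
#'
#' Replaces by-eye alignment reading: maximal gap runs in the copy are
#' deletions, gap runs in the reference are insertions, and coordinates are
#' reported in ungapped 1-based reference positions. Indels in repeat context
#' are left-normalized, with the span of equivalent placements recorded in
#' `amb_start`/`amb_end` (the location ambiguity the repeat induces).
#'
#' @param aligned_ref,aligned_copy Gap-aligned sequences of equal length
#'   (gap character `-`).
#' @return A list with `events` (an [indel_events()] data frame) and
#'   `substitutions` (1-based ungapped reference positions where both
#'   sequences have bases that differ).
#' @export
extract_events <- function(aligned_ref, aligned_copy) {
  r <- strsplit(.as_seq(aligned_ref), "", fixed = TRUE)[[1]]
  c_ <- strsplit(.as_seq(aligned_copy), "", fixed = TRUE)[[1]]
  if (base::length(r) != base::length(c_))
    stop("aligned sequences must have equal length", call. = FALSE)
  both_gap <- r == "-" & c_ == "-"
  if (any(both_gap)) {
    warning("dropping ", sum(both_gap), " column(s) gapped in both sequences",
            call. = FALSE)
    r <- r[!both_gap]; c_ <- c_[!both_gap]
  }
  ref_pos <- cumsum(r != "-")          # ungapped ref position per column
  ref_bases <- r[r != "-"]
  kind <- character(0); start <- integer(0); len <- integer(0)
  seqs <- character(0); ambs <- integer(0); ambe <- integer(0)
  n <- base::length(r)
  i <- 1L
  while (i <= n) {
    if (c_[i] == "-") {                # deletion run in the copy
      j <- i
      while (j < n && c_[j + 1L] == "-") j <- j + 1L
      s <- ref_pos[i]; l <- j - i + 1L
      nm <- .normalize_deletion(ref_bases, s, l)
      kind <- c(kind, "deletion"); start <- c(start, nm$start)
      len <- c(len, l); seqs <- c(seqs, NA_character_)
      ambs <- c(ambs, nm$amb_start); ambe <- c(ambe, nm$amb_end)
      i <- j + 1L
    } else if (r[i] == "-") {          # insertion run in the copy
      j <- i
      while (j < n && r[j + 1L] == "-") j <- j + 1L
      anchor <- ref_pos[i] + 1L        # before the next reference base
      ins <- paste(c_[i:j], collapse = "")
      nm <- .normalize_insertion(ref_bases, anchor, ins)
      kind <- c(kind, "insertion"); start <- c(start, nm$start)
      len <- c(len, j - i + 1L); seqs <- c(seqs, nm$seq)
      ambs <- c(ambs, nm$amb_start); ambe <- c(ambe, nm$amb_end)
      i <- j + 1L
    } else i <- i + 1L
  }
  subs <- ref_pos[r != "-" & c_ != "-" & r != c_]
  list(events = indel_events(kind, start, len, seqs, ambs, ambe),
       substitutions = as.integer(subs))
}

#' Build a gapped pairwise alignment from a known event log
#'
#' The exact inverse view of [extract_events()] for sequences whose history
#' is known: no heuristic alignment is involved, so alignment correctness is
#' by construction.
#'
#' @param ref_cds Reference sequence.
#' @param events An [indel_events()] data frame describing the copy.
#' @param copy Optional derived sequence; default `apply_events(ref_cds,
#'   events)`. Supply it when substitutions were applied on top of the
#'   events.
#' @return Named character vector `c(ref = ..., copy = ...)` of equal-length
#'   gapped sequences.
#' @export
events_to_alignment <- function(ref_cds, events, copy = NULL) {
  ref <- .as_seq(ref_cds)
  L <- nchar(ref)
  .validate_events(events, L)
  if (is.null(copy)) copy <- apply_events(ref, events)
  copy <- .as_seq(copy)
  rb <- strsplit(ref, "", fixed = TRUE)[[1]]
  cb <- strsplit(copy, "", fixed = TRUE)[[1]]
  keep <- rep(TRUE, L)
  ins_before <- character(L + 1L)
  for (i in seq_len(nrow(events))) {
    if (events$kind[i] == "deletion")
      keep[events$ref_start[i]:(events$ref_start[i] + events$length[i] - 1L)] <- FALSE
    else {
      p <- events$ref_start[i]
      ins_before[p] <- paste0(ins_before[p], events$inserted_seq[i])
    }
  }
  ra <- character(0); ca <- character(0)
  ci <- 1L
  for (p in seq_len(L + 1L)) {
    ni <- nchar(ins_before[p])
    if (ni > 0L) {
      ra <- c(ra, strrep("-", ni))
      ca <- c(ca, substr(copy, ci, ci + ni - 1L))
      ci <- ci + ni
    }
    if (p <= L) {
      ra <- c(ra, rb[p])
      if (keep[p]) {
        ca <- c(ca, substr(copy, ci, ci))
        ci <- ci + 1L
      } else ca <- c(ca, "-")
    }
  }
  c(ref = paste(ra, collapse = ""), copy = paste(ca, collapse = ""))
}

#' Read / write indel event tables as TSV
#'
#' Columns `kind`, `ref_start`, `length`, `inserted_seq` (and, if present,
#' `copy`, `amb_start`, `amb_end`).
#'
#' @param events An [indel_events()] data frame (a `copy` column is allowed
#'   for per-copy logs).
#' @param path File path.
#' @return `read_events` returns an [indel_events()] data frame;
#'   `write_events` returns `path` invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", na.strings = "")
  ev <- indel_events(df$kind, as.integer(df$ref_start), as.integer(df$length),
                     if ("inserted_seq" %in% names(df)) df$inserted_seq else NA,
                     if ("amb_start" %in% names(df)) as.integer(df$amb_start) else NA,
                     if ("amb_end" %in% names(df)) as.integer(df$amb_end) else NA)
  if ("copy" %in% names(df)) ev$copy <- df$copy[order(as.integer(df$ref_start), df$kind)]
  ev
}
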