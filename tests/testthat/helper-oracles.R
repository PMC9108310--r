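# Independent brute-force oracles used to freeze expected values.

ORACLE_BASES <- c("A", "C", "G", "T")
ORACLE_STOPS <- c("TAA", "TAG", "TGA")

# Nei-Gojobori pathway oracle for a single codon pair: enumerate every
# ordering of the differing positions by explicit recursion, drop orderings
# that pass through a stop codon (keep all if every one does), and average
# synonymous/nonsynonymous step counts. Sites: per position, the fraction
# of the three possible changes that are synonymous (changes to stops are
# nonsynonymous).
oracle_ng_codon_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  s <- 0
  for (j in 1:3) {
    for (b in setdiff(ORACLE_BASES, substr(codon, j, j))) {
      m <- codon
      substr(m, j, j) <- b
      if (!(m %in% ORACLE_STOPS) && gc[[m]] == gc[[codon]]) s <- s + 1 / 3
    }
  }
  c(syn = s, nonsyn = 3 - s)
}

oracle_ng_codon_diffs <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(diff_pos) == 0L) return(c(sd = 0, nd = 0))
  paths <- list()
  recurse <- function(cur, remaining, sd, nd, through_stop) {
    if (length(remaining) == 0L) {
      paths[[length(paths) + 1L]] <<- list(sd = sd, nd = nd,
                                           blocked = through_stop)
      return(invisible())
    }
    for (j in remaining) {
      nxt <- cur
      substr(nxt, j, j) <- substr(c2, j, j)
      syn <- !(cur %in% ORACLE_STOPS) && !(nxt %in% ORACLE_STOPS) &&
        gc[[cur]] == gc[[nxt]]
      recurse(nxt, setdiff(remaining, j),
              sd + as.integer(syn), nd + as.integer(!syn),
              through_stop || nxt %in% ORACLE_STOPS)
    }
  }
  recurse(c1, diff_pos, 0L, 0L, FALSE)
  blocked <- vapply(paths, `[[`, logical(1), "blocked")
  use <- if (all(blocked)) seq_along(paths) else which(!blocked)
  c(sd = mean(vapply(paths[use], `[[`, 0, "sd")),
    nd = mean(vapply(paths[use], `[[`, 0, "nd")))
}

# Brute-force per-base codon walk: for a single deletion of `len` bases at
# reference position `s`, map every derived base back to its reference
# origin and report the first product codon holding a base whose reading
# frame no longer matches the canonical frame.
oracle_onset_codon <- function(s, len, ref_length) {
  derived_len <- ref_length - len
  ref_of <- ifelse(seq_len(derived_len) < s, seq_len(derived_len),
                   seq_len(derived_len) + len)
  n_codons <- ceiling(derived_len / 3)
  for (cd in seq_len(n_codons)) {
    idx <- (3 * cd - 2):min(3 * cd, derived_len)
    if (any((ref_of[idx] - idx) %% 3 != 0)) return(cd)
  }
  NA_integer_
}

# Enumerate every placement of a `len`-base deletion in `ref` that yields
# the same derived sequence as deleting at `s` (repeat-induced ambiguity).
oracle_equivalent_deletions <- function(ref, s, len) {
  target <- paste0(substr(ref, 1, s - 1), substr(ref, s + len, nchar(ref)))
  which(vapply(seq_len(nchar(ref) - len + 1L), function(p)
    paste0(substr(ref, 1, p - 1), substr(ref, p + len, nchar(ref))) == target,
    logical(1)))
}

# Random coding-like sequence for round-trip property tests.
random_ref <- function(n, seed) {
  set.seed(seed)
  paste(sample(ORACLE_BASES, n, replace = TRUE), collapse = "")
}
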