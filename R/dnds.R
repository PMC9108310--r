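#' Nei-Gojobori dN/dS by pathway counting
#'
#' The 1986 counting method: each codon contributes synonymous site counts
#' `s = sum_j f_j` where `f_j` is the fraction of the three possible changes
#' at position `j` that are synonymous (changes to stop codons count as
#' nonsynonymous), and `n = 3 - s` nonsynonymous sites. Differences between
#' a codon pair are apportioned by averaging synonymous/nonsynonymous steps
#' over all mutational pathways between the two codons, excluding pathways
#' that pass through stop codons (all pathways are used if every one is
#' blocked). Proportions are corrected for multiple hits with the
#' Jukes-Cantor formula `d = -3/4 log(1 - 4/3 p)`.
#'
#' @name nei-gojobori
#' @keywords internal
NULL

.BASES <- c("A", "C", "G", "T")

.is_stop <- function(codon) codon %in% c("TAA", "TAG", "TGA")

.ng_cache <- new.env(parent = emptyenv())

# Synonymous/nonsynonymous potential sites of one codon (memoized).
.ng_sites <- function(codon) {
  hit <- .ng_cache[[codon]]
  if (!is.null(hit)) return(hit)
  res <- .ng_sites_compute(codon)
  .ng_cache[[codon]] <- res
  res
}

.ng_sites_compute <- function(codon) {
  if (.is_stop(codon)) return(c(s = 0, n = 0))
  aa <- Biostrings::GENETIC_CODE[[codon]]
  s <- 0
  for (j in 1:3) {
    for (b in setdiff(.BASES, substr(codon, j, j))) {
      mut <- codon
      substr(mut, j, j) <- b
      if (!.is_stop(mut) && Biostrings::GENETIC_CODE[[mut]] == aa)
        s <- s + 1 / 3
    }
  }
  c(s = s, n = 3 - s)
}

# Average synonymous/nonsynonymous differences between two codons over all
# stop-free mutational pathways (all pathways if none is stop-free).
# Memoized over the 64 x 64 codon pairs.
.ng_diffs <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- .ng_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- .ng_diffs_compute(c1, c2)
  .ng_cache[[key]] <- res
  res
}

.ng_diffs_compute <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  ndiff <- base::length(pos)
  if (ndiff == 0L) return(c(sd = 0, nd = 0))
  perms <- if (ndiff == 1L) list(pos) else
    if (ndiff == 2L) list(pos, rev(pos)) else
      lapply(list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1)), function(o) pos[o])
  path_sd <- numeric(0); path_nd <- numeric(0); blocked <- logical(0)
  for (ord in perms) {
    cur <- c1; sd_ <- 0; nd_ <- 0; blk <- FALSE
    for (j in ord) {
      nxt <- cur
      substr(nxt, j, j) <- substr(c2, j, j)
      if (.is_stop(nxt)) blk <- TRUE
      if (!.is_stop(cur) && !.is_stop(nxt) &&
          Biostrings::GENETIC_CODE[[cur]] == Biostrings::GENETIC_CODE[[nxt]])
        sd_ <- sd_ + 1 else nd_ <- nd_ + 1
      cur <- nxt
    }
    path_sd <- c(path_sd, sd_); path_nd <- c(path_nd, nd_)
    blocked <- c(blocked, blk)
  }
  use <- if (all(blocked)) rep(TRUE, base::length(blocked)) else !blocked
  c(sd = mean(path_sd[use]), nd = mean(path_nd[use]))
}

.jc_correct <- function(p) {
  if (p >= 0.75) return(NA_real_)
  if (p == 0) return(0)
  -0.75 * log(1 - 4 * p / 3)
}

# Core pairwise computation on two equal-length gapped sequences whose frame
# follows the reference codon structure of seq1.
.ng_pair <- function(a1, a2, region = NULL) {
  b1 <- strsplit(.as_seq(a1), "", fixed = TRUE)[[1]]
  b2 <- strsplit(.as_seq(a2), "", fixed = TRUE)[[1]]
  if (base::length(b1) != base::length(b2))
    stop("aligned sequences must have equal length", call. = FALSE)
  # reference codon index per column (NA in columns where seq1 is gapped)
  rp <- cumsum(b1 != "-")
  codon_idx <- ifelse(b1 != "-", (rp - 1L) %/% 3L + 1L, NA_integer_)
  n_codons <- max(0L, rp[base::length(rp)] %/% 3L)
  idx <- if (is.null(region)) seq_len(n_codons) else region
  S <- N <- Sd <- Nd <- 0
  used <- 0L
  for (ci in idx) {
    cols <- which(!is.na(codon_idx) & codon_idx == ci)
    if (base::length(cols) != 3L) next
    # skip codons interrupted by insertion columns in the copy
    if (any(diff(cols) != 1L)) next
    c1 <- paste(b1[cols], collapse = "")
    c2 <- paste(b2[cols], collapse = "")
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
    if (.is_stop(c1) || .is_stop(c2)) next
    st1 <- .ng_sites(c1); st2 <- .ng_sites(c2)
    S <- S + (st1["s"] + st2["s"]) / 2
    N <- N + (st1["n"] + st2["n"]) / 2
    d <- .ng_diffs(c1, c2)
    Sd <- Sd + d["sd"]; Nd <- Nd + d["nd"]
    used <- used + 1L
  }
  list(S = unname(S), N = unname(N), Sd = unname(Sd), Nd = unname(Nd),
       codons_used = used)
}

#' Nei-Gojobori dN/dS for a codon alignment
#'
#' @param codon_alignment Named character vector (or `DNAStringSet`) of two
#'   or more equal-length gap-aligned sequences. The first sequence defines
#'   the codon frame (its ungapped positions are grouped in consecutive
#'   triplets). Codons containing gaps, insertions, ambiguous bases or stop
#'   codons are skipped.
#' @param region Optional integer vector of codon indices (in the frame of
#'   the first sequence) to restrict the analysis to, e.g. `1:88`.
#' @return A list of class `dnds_result`: site counts `S`, `N`, difference
#'   counts `Sd`, `Nd`, proportions `ps`, `pn`, Jukes-Cantor distances `ds`,
#'   `dn`, the `ratio` dN/dS (`NA` with `ratio_defined = FALSE` when
#'   `ds = 0`), and `codons_used`. For more than two sequences, counts are
#'   summed over all pairs.
#' @examples
#' nei_gojobori_dnds(c(a = "ATGAAA", b = "ATGAAG"))  # one synonymous change
#' @export
nei_gojobori_dnds <- function(codon_alignment, region = NULL) {
  if (inherits(codon_alignment, "XStringSet"))
    codon_alignment <- stats::setNames(as.character(codon_alignment),
                                       names(codon_alignment))
  if (base::length(codon_alignment) < 2L)
    stop("need at least two sequences", call. = FALSE)
  if (!is.null(region) && base::length(region) < 1L)
    stop("region must contain at least one codon", call. = FALSE)
  S <- N <- Sd <- Nd <- 0; used <- 0L
  nseq <- base::length(codon_alignment)
  for (i in seq_len(nseq - 1L)) for (j in (i + 1L):nseq) {
    pr <- .ng_pair(codon_alignment[[i]], codon_alignment[[j]], region)
    S <- S + pr$S; N <- N + pr$N; Sd <- Sd + pr$Sd; Nd <- Nd + pr$Nd
    used <- used + pr$codons_used
  }
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  ds <- if (is.na(ps)) NA_real_ else .jc_correct(ps)
  dn <- if (is.na(pn)) NA_real_ else .jc_correct(pn)
  defined <- !is.na(ds) && !is.na(dn) && ds > 0
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
                 ds = ds, dn = dn,
                 ratio = if (defined) dn / ds else NA_real_,
                 ratio_defined = defined, codons_used = used),
            class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf("<dnds_result> dn=%.4g ds=%.4g dn/ds=%s (S=%.1f N=%.1f, %d codons)\n",
              x$dn, x$ds,
              if (x$ratio_defined) sprintf("%.3f", x$ratio) else "undefined",
              x$S, x$N, x$codons_used))
  invisible(x)
}

#' Compare two chi-square statistics by their per-df ratio
#'
#' Forms `F = (chi_a/df_a) / (chi_b/df_b)`, distributed as F(df_a, df_b)
#' under the hypothesis that both statistics measure the same underlying
#' signal, and reports the lower-tail probability `P(F <= observed)`. The
#' lower-tail convention is deliberate: a small tail probability indicates
#' the first statistic is *weaker* per degree of freedom than the second,
#' while values near 0.5 indicate comparable signals (e.g. chi-squares of
#' 10.66 and 9.59 on 2 df each give F = 1.11, p = 0.53).
#'
#' @param chi_a,chi_b Positive chi-square statistics.
#' @param df_a,df_b Their degrees of freedom (positive).
#' @return A list with `F`, `df` and `p` (lower tail).
#' @export
chisq_ratio_test <- function(chi_a, df_a, chi_b, df_b) {
  if (any(c(chi_a, chi_b) <= 0)) stop("statistics must be positive", call. = FALSE)
  if (any(c(df_a, df_b) <= 0)) stop("degrees of freedom must be positive", call. = FALSE)
  Fv <- (chi_a / df_a) / (chi_b / df_b)
  list(F = Fv, df = c(df_a, df_b), p = stats::pf(Fv, df_a, df_b))
}
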