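---
title: "Models and methods behind retrodrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind retrodrift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrodrift)
```

`retrodrift` asks a single scientific question from three directions: is
the expansion of *TP53* retrogene (RTG) copies in the African elephant
better explained by selection for cancer suppression or by neutral
duplication and drift? This vignette documents the models, the parameter
choices, and the design decisions taken where the problem left the design
genuinely open.

## 1. The evolutionary multistage model of carcinogenesis

For small lifetime risks the multistage model gives

$$p = C\,(u\,k\,T)^M,$$

where $C$ counts at-risk stem cells, $u$ is the somatic mutation rate per
gene per cell division, $k$ the stem-cell divisions per year, $T$ the
reproductive lifespan in years, and $M$ the number of driver mutations a
cell lineage must accumulate. `cancer_risk()` evaluates the formula and
warns above $p = 0.1$, where the small-$p$ approximation degrades.

**Calibration and solving.** The evolutionary reading fixes a target risk
($p = 0.001$ by default, configurable) for a small hyrax-like reference
species and asks what a larger, longer-lived descendant must change.
`calibrate_u()` inverts the formula in closed form,
$u = (p/C)^{1/M} / (kT)$; `solve_M()` then treats $M$ as continuous,
$M = \ln(p/C)/\ln(ukT)$, and `solve_u_fold()` holds $M$ fixed and reduces
$u$. $M_\text{add}$ is reported at one decimal and fold-reductions as
rounded integers, matching how such tables are conventionally printed,
while full precision is kept internally.

**Parameters.** Stem-cell counts and division rates are tabulated for
human tissue (colorectal $C = 2\times10^8$, $k = 73$/yr, $M = 4$;
hepatocellular $C = 3.01\times10^8$, $k = 0.9125$/yr, $M = 2$; esophageal
$C = 6{,}652{,}800$, $k = 33.2$/yr, $M = 3$), and $C$ scales
proportionally with body mass (hyrax 2.95 kg, elephant 3940 kg, manatee
467 kg, human 58.7 kg; reproductive lifespans 11, 65, 40, 55 yr).
Reproductive rather than total lifespan is used because it is the window
over which selection against cancer acts.

**The metabolic-scaling anchor.** Kleiber's law motivates an optional
scaling of the division rate, $k \propto C^{-0.15}$. Two conventions are
possible: anchoring the scaling at the species whose $k$ is tabulated
(human) or at the calibration reference (hyrax). These differ unless the
scaling is *chained*, i.e. $k_s = k_\text{human} (C_s/C_\text{human})^{-0.15}$
for every species including the hyrax. Only the chained convention
reproduces the published metabolic-mode baseline mutation rates
($2.5\times10^{-6}$, $5.2\times10^{-7}$, $2.6\times10^{-6}$), so
`effective_k()` adopts it; the anchor species is exposed as an argument.

**Documented anomalies.** Under this (or any single) convention the
published metabolic-mode $M_\text{add}$ cells, and the elephant esophageal
no-metabolic-effect $M_\text{add}$ cell, cannot all be reproduced — the
elephant cells behave as if anchored at the hyrax, the manatee cells at
the human, and the esophageal cell as if computed with the metabolic-mode
baseline $u$. Rather than special-casing cells, `compare_emmc_table()`
computes every cell under the one declared convention and flags these
cells as `excluded`, with a warning; they are never silently matched. The
packaged printed values (`inst/extdata/table1_printed.tsv`) are used only
by the comparison sheet, never by any computation.

## 2. Neutral duplication–drift

Neutral mutations fix at the mutation rate, so with a duplication
probability $U_\text{dup}$ per copy per generation, $n$ fixed copies gain
new ones at rate $nU_\text{dup}$: a pure-birth (Yule) process with
$\mathbb{E}[n(t)] = n_0 e^{U_\text{dup} t}$ and, from $n_0 = 1$, a
geometric copy-number distribution with success parameter
$e^{-U_\text{dup}t}$. This predicts a linear relation between log copy
number and time; `fit_log_slope()` fits it by ordinary least squares and
`estimate_Udup()` converts a per-year slope with the generation time
(25 yr for elephants by default). **Natural logarithms are used
throughout**; any consistent base would cancel in the estimator, but the
slope itself is reported in natural-log units.

`simulate_drift()` implements discrete generations with either exact
Bernoulli thinning (each copy duplicates with probability $U_\text{dup}$)
or a Poisson($nU_\text{dup}$) increment, the default for speed; the two
agree to $O(U_\text{dup}^2)$. `simulate_genealogy()` instead draws the
exact exponential waiting times of the continuous-time Yule process
($\text{Exp}(iU_\text{dup})$ between the $i$-th and $(i{+}1)$-th copy)
and a uniformly chosen duplicating lineage, returning an `ape::phylo`
tree with branch lengths in generations. The waiting-time route is used
for parameter-recovery simulations at realistic rates
($U_\text{dup} \sim 10^{-6}$, where per-generation iteration over
millions of generations per clade would be wasteful); the agreement of
the two routes with the closed forms is itself under test. No copy-loss,
polymorphism or effective-population-size dynamics are modeled: fixation
is treated as instantaneous, as the rate argument itself does. The
elephant-clade time origin defaults to 60 My where needed, configurable.

## 3. Retrogene ORF decay

**Coordinates.** All indel events live in 1-based reference coordinates
("ref bp") on the canonical CDS; inclusive ranges; product codons are
1-based. A deletion at position $s$ of length $\ell$ removes bases
$s..s{+}\ell{-}1$; an insertion places its bases immediately before $s$.

**Indel normalization.** A deletion inside a repeat has no unique
placement. `extract_events()` left-normalizes every indel and records the
span of equivalent placements (`amb_start`/`amb_end`) — the fixture's
1-bp deletion in the homopolymer around bp 291–294 is the motivating
case, where the placement is genuinely ambiguous.

**Frame tracking.** `frame_track()` is purely geometric: the cumulative
net indel length mod 3 defines the frame offset, a segment boundary falls
at every offset-changing event, and the onset codon is
$\lfloor(\text{derived position}-1)/3\rfloor + 1$. With the basal
deletions (15 bp at 229, 2 bp at 487) the shift begins at product codon
158; the compensating 1-bp/2-bp pair at 635/671 scrambles exactly codons
212–223 (12 codons) before restoring frame; adding the 7-bp deletion at
728 leaves an unrestored shift from codon 242.

**Termination rule.** `orf_report()` translates segment by segment under
the standard nuclear code. A scrambled segment whose stop codon arrives
before the compensating indel terminates the product there — the
canonical-codon count is frozen at the in-frame codons read before that
segment. A scrambled segment traversed without a stop contributes its
codons to the scrambled tally and translation continues in the restored
frame. This rule is necessary rather than convenient: the full basal
elephant event set deletes $15{+}2{+}1{+}2{+}7 = 27$ bp, which is
frame-neutral in total, so no purely geometric notion of an "unrestored"
shift can yield the 157/390 truncation — it is the stop codon read in the
shifted frame that truncates the product. A missing ATG start is flagged,
not fatal (one fixture copy deliberately loses it).

**dN/dS.** `nei_gojobori_dnds()` implements the 1986 pathway-counting
method: per-position synonymous site fractions (changes to stops counted
as nonsynonymous), differences averaged over all stop-free mutational
pathways between codon pairs (all pathways if every one is blocked), and
Jukes–Cantor correction $d = -\tfrac34\ln(1-\tfrac43 p)$. Codons with
gaps, insertions or ambiguous bases are skipped; `ds = 0` yields an
explicitly flagged undefined ratio. The test suite checks the counts
against an independently written brute-force pathway enumeration, and
checks that neutrally evolved pairs give a median ratio near 1.

**Chi-square ratio.** `chisq_ratio_test()` forms
$F = (\chi^2_a/df_a)/(\chi^2_b/df_b)$ and reports the **lower-tail**
probability $P(F \le F_\text{obs})$. For two equally strong selection
signals the statistic sits near 1 and the lower tail near 0.5
(e.g. $F(2,2) = 1.11$, $p = 0.53$); the upper tail would report 0.47. The
lower-tail convention is stated here prominently because both are
defensible.

## 4. The synthetic-data generator

`make_reference_cds()` builds a random CDS — ATG start, random sense
codons at the configured GC fraction, one terminal stop, no internal
in-frame stops. At the default length (1173 bp = 390 codons + stop) it
also embeds the sequence features the deterministic fixture needs, all of
which emulate documented properties of the real elephant *TP53* region:

- a homopolymer across bp 291–294, making the 1-bp deletion there
  genuinely ambiguous in placement;
- a stop codon at bp 519–521 *read in the frame shifted by the basal
  17 bp of deletions* (it is this stop that truncates the basal elephant
  RTG product at 40% of the canonical protein);
- the stop pair at bp 1016–1018/1022–1024 read in the frame shifted by
  the net 10-bp pre-clade deletions;
- a stop-free shifted-frame window between bp 635 and 671, so the
  compensated 12-codon scramble is traversed rather than terminated.

`rtg_family_fixture()` applies the documented per-copy deletion sets (all
21 copies share del1\@635 + del2\@671; hyrax and the 19 elephant copies
add del7\@728; the elephant copies add del15\@229 + del2\@487; copies
8–19 add del1\@291 and del1\@574; copies 2–5 del1\@597; copies 3–5
del1\@813) and background substitutions at ~0.05/site, applied
independently per copy. Substitutions avoid the engineered windows and
any change that would create a stop codon in any local reading frame, so
the truncation arithmetic above is deterministic by construction, not by
luck. The reference's 3-bp insertion at 882–884 is stored mechanically as
a shared 3-bp deletion in every copy's log (reference coordinates include
the inserted bases) and labeled a reference-lineage insertion in the
bundle notes. The documented 25-bp and 5-bp insertions elsewhere in the
real family are not coordinate-localized and are omitted, noted in the
manifest.

`evolve_family()` is the stochastic counterpart for property tests:
uniform substitutions (no selection) and optional indels down a
duplication genealogy, with exact per-tip event logs. Alignments are
always derived from the known logs — no heuristic aligner — so alignment
correctness is by construction. Simplifications: indels never nest inside
earlier indels on the same lineage, substitutions are not placed inside
inserted sequence, and fixture substitutions are independent across
copies rather than phylogenetically correlated. Consequently the fixture
family reproduces the published *coordinate* arithmetic exactly but not,
for example, the published count of 445 substituted alignment sites,
which depends on shared ancestry; passing tests demonstrate correctness
of the bookkeeping, not realism of the mutational process.

## 5. Numerical choices and test scale

- Calibration round-trips are checked to $10^{-12}$ and solver
  consistency to $10^{-9}$; reproduction of printed table cells uses a
  ±5% relative tolerance on pre-rounding values, since the rounding of
  weights and intermediates in the original spreadsheet is unrecoverable.
- Simulator checks use $10^4$ replicates for the geometric
  goodness-of-fit at $U_\text{dup}t = 1$, 4000 replicates per setting for
  mean comparisons (3 standard errors), 100 19-copy clades for parameter
  recovery (median within 25%), and 50 replicate pairs for the dN/dS
  neutrality check (median within 10% of 1). These sizes give stable
  verdicts at fixed seeds while keeping the default suite fast.
- All randomness flows through explicit integer seeds; generator and
  simulator calls restore the caller's RNG state.
- Degenerate inputs are errors with named offenders (overlapping or
  out-of-bounds deletions, non-increasing trajectory times,
  $ukT \ge 1$ in the solver) except where the science says otherwise
  (missing start codon: flag; $ds = 0$: flagged undefined ratio;
  both-gap alignment columns: dropped with a warning).

## 6. Known limitations

- $M$ is solved as a continuous quantity; no integer-constrained
  optimization is attempted, and $C$, $k$ are inputs, not derived from
  tissue biology.
- The drift model has no selection coefficients, no within-population
  polymorphism, and no copy loss.
- Codon-model likelihoods (PAML-style M0/M1/M2/M8 fits), tree inference
  and splice-site scanning are out of scope; only the downstream
  chi-square-ratio comparison and the counting-method dN/dS are provided.
- The generator makes no attempt at codon-usage or CpG mutation realism.
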