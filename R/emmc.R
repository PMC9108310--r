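#' Evolutionary multistage model of carcinogenesis (EMMC)
#'
#' Under the multistage model, a cancer initiates once a single cell lineage
#' has accumulated `M` tissue-specific driver mutations. For small risks the
#' lifetime probability of initiation is
#' \deqn{p = C (u k T)^M}
#' where `C` is the number of at-risk stem cells, `u` the somatic mutation
#' rate per gene per cell division, `k` the number of stem-cell divisions per
#' year, and `T` the reproductive lifespan in years. The evolutionary reading
#' of the model asks how much `M` must increase, or `u` decrease, for a
#' species that evolved to be larger and/or longer-lived to hold its lifetime
#' risk at the level of its small-bodied ancestor.
#'
#' @name emmc
#' @keywords internal
NULL

#' Construct a cancer parameter set
#'
#' Bundles the multistage parameters of one cancer type as tabulated for a
#' reference species (conventionally human): the stem-cell count `C_ref`, the
#' stem-cell division rate `k_ref`, the baseline driver-mutation count
#' `M_base`, and the target lifetime risk `p_target`.
#'
#' @param name Label for the cancer type.
#' @param C_ref Stem-cell count in the reference species (cells, > 0).
#' @param k_ref Stem-cell divisions per year in the reference species (> 0).
#' @param M_base Baseline integer driver-mutation count (>= 1).
#' @param p_target Target lifetime risk probability (default 0.001, i.e. 0.1%).
#' @return An object of class `cancer_spec`.
#' @examples
#' colorectal <- cancer_spec("colorectal", C_ref = 2e8, k_ref = 73, M_base = 4)
#' @export
cancer_spec <- function(name, C_ref, k_ref, M_base, p_target = 0.001) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(C_ref) || length(C_ref) != 1L || C_ref <= 0)
    stop("C_ref must be a single positive number", call. = FALSE)
  if (!is.numeric(k_ref) || length(k_ref) != 1L || k_ref <= 0)
    stop("k_ref must be a single positive number", call. = FALSE)
  if (!is.numeric(M_base) || length(M_base) != 1L || M_base < 1 ||
      M_base != round(M_base))
    stop("M_base must be a positive integer", call. = FALSE)
  if (!is.numeric(p_target) || p_target <= 0 || p_target >= 1)
    stop("p_target must lie in (0, 1)", call. = FALSE)
  if (p_target >= C_ref)
    stop("p_target must be smaller than C_ref", call. = FALSE)
  structure(
    list(name = name, C_ref = C_ref, k_ref = k_ref,
         M_base = as.integer(M_base), p_target = p_target),
    class = "cancer_spec")
}

#' Construct a species life-history profile
#'
#' @param name Species label.
#' @param weight_kg Average adult body mass in kg (> 0). Stem-cell counts are
#'   assumed proportional to body mass.
#' @param T_years Reproductive lifespan in years (> 0): birth to the cessation
#'   of reproductive effort, the window over which selection against cancer
#'   acts.
#' @return An object of class `species_profile`.
#' @examples
#' hyrax <- species_profile("rock hyrax", weight_kg = 2.95, T_years = 11)
#' @export
species_profile <- function(name, weight_kg, T_years) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(weight_kg) || length(weight_kg) != 1L || weight_kg <= 0)
    stop("weight_kg must be a single positive number", call. = FALSE)
  if (!is.numeric(T_years) || length(T_years) != 1L || T_years <= 0)
    stop("T_years must be a single positive number", call. = FALSE)
  structure(list(name = name, weight_kg = weight_kg, T_years = T_years),
            class = "species_profile")
}

#' Metabolic-rate scaling mode
#'
#' Kleiber's law implies metabolic rate per unit mass declines with body
#' size; at its maximal plausible effect the stem-cell division rate scales
#' as `C^-0.15`. When enabled, the division rate of each species is scaled by
#' `(C_species / C_anchor)^exponent` relative to the species whose `k` is
#' tabulated (the chained convention; see the methods vignette).
#'
#' @param enabled Logical; apply the scaling?
#' @param exponent Scaling power; fixed at -0.15 when enabled, 0 otherwise.
#' @return An object of class `metabolic_mode`.
#' @export
metabolic_mode <- function(enabled = FALSE, exponent = if (enabled) -0.15 else 0) {
  stopifnot(is.logical(enabled), length(enabled) == 1L)
  if (!enabled && exponent != 0)
    stop("exponent must be 0 when the metabolic mode is disabled", call. = FALSE)
  structure(list(enabled = enabled, exponent = exponent),
            class = "metabolic_mode")
}

#' @export
print.cancer_spec <- function(x, ...) {
  cat(sprintf("<cancer_spec> %s: C_ref=%.4g, k_ref=%.4g /yr, M_base=%d, p_target=%g\n",
              x$name, x$C_ref, x$k_ref, x$M_base, x$p_target))
  invisible(x)
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("<species_profile> %s: %.4g kg, T=%.4g yr\n",
              x$name, x$weight_kg, x$T_years))
  invisible(x)
}

#' Lifetime cancer risk under the multistage model
#'
#' Evaluates `p = C (u k T)^M`. The approximation assumes small `p`; a
#' warning is issued above 0.1.
#'
#' @param C Stem-cell count (> 0).
#' @param u Somatic mutation rate per gene per cell division (>= 0).
#' @param k Stem-cell divisions per year (> 0).
#' @param T_years Reproductive lifespan in years (> 0).
#' @param M Driver-mutation count (> 0; treated as continuous).
#' @return Lifetime risk (probability).
#' @examples
#' cancer_risk(C = 5, u = 0.1, k = 1, T_years = 1, M = 2)  # 0.05
#' @export
cancer_risk <- function(C, u, k, T_years, M) {
  if (!all(is.finite(c(C, u, k, T_years, M))))
    stop("all arguments must be finite", call. = FALSE)
  if (C <= 0 || k <= 0 || T_years <= 0 || M <= 0)
    stop("C, k, T_years and M must be positive", call. = FALSE)
  if (u < 0) stop("u must be non-negative", call. = FALSE)
  p <- C * (u * k * T_years)^M
  if (p > 0.1)
    warning("risk exceeds 0.1; the small-p approximation p = C(ukT)^M degrades",
            call. = FALSE)
  p
}

#' Scale a stem-cell count by body mass
#'
#' Stem-cell populations are assumed proportional to body mass, so a cancer's
#' tabulated `C_ref` is scaled by the species/reference weight ratio.
#'
#' @param cancer A [cancer_spec()].
#' @param species,reference [species_profile()] objects; `reference` is the
#'   species for which `C_ref` is tabulated.
#' @return Stem-cell count for `species`.
#' @export
scale_C <- function(cancer, species, reference) {
  stopifnot(inherits(cancer, "cancer_spec"),
            inherits(species, "species_profile"),
            inherits(reference, "species_profile"))
  cancer$C_ref * species$weight_kg / reference$weight_kg
}

#' Effective stem-cell division rate under metabolic scaling
#'
#' With the metabolic mode disabled the tabulated `k_ref` is returned
#' unchanged. Enabled, the division rate is scaled as
#' `k_ref * (C_species / C_anchor)^exponent`, anchored at the species whose
#' `k` is tabulated, so scalings chain consistently across species.
#'
#' @inheritParams scale_C
#' @param mode A [metabolic_mode()].
#' @param reference The anchor species whose `k_ref` (and `C_ref`) are
#'   tabulated.
#' @return Divisions per year for `species`.
#' @export
effective_k <- function(cancer, species, mode, reference) {
  stopifnot(inherits(mode, "metabolic_mode"))
  if (!mode$enabled) return(cancer$k_ref)
  C_sp <- scale_C(cancer, species, reference)
  cancer$k_ref * (C_sp / cancer$C_ref)^mode$exponent
}

#' Calibrate the somatic mutation rate on the reference species
#'
#' Chooses `u` so that the reference (ancestral, hyrax-like) species has
#' lifetime risk exactly `p_target` at the cancer's baseline `M`:
#' `u = (p_target / C_ref_species)^(1/M_base) / (k_eff * T_ref)`.
#'
#' @param cancer A [cancer_spec()].
#' @param reference_species The hyrax-like anchor [species_profile()] on which
#'   risk is pinned to `p_target`.
#' @param mode A [metabolic_mode()].
#' @param tab_species The species whose `C_ref`/`k_ref` are tabulated
#'   (default `reference_species`, i.e. the tabulated values already refer to
#'   the calibration species). Pass the human profile when using
#'   human-tabulated parameters for a hyrax calibration.
#' @return Somatic mutation rate per gene per cell division.
#' @examples
#' colorectal <- cancer_spec("colorectal", 2e8, 73, 4)
#' hyrax <- species_profile("rock hyrax", 2.95, 11)
#' human <- species_profile("human", 58.7, 55)
#' calibrate_u(colorectal, hyrax, metabolic_mode(FALSE), tab_species = human)
#' @export
calibrate_u <- function(cancer, reference_species, mode = metabolic_mode(FALSE),
                        tab_species = reference_species) {
  stopifnot(inherits(cancer, "cancer_spec"),
            inherits(reference_species, "species_profile"))
  C_ref_sp <- scale_C(cancer, reference_species, tab_species)
  k_eff <- effective_k(cancer, reference_species, mode, tab_species)
  (cancer$p_target / C_ref_sp)^(1 / cancer$M_base) /
    (k_eff * reference_species$T_years)
}

#' Solve for the driver-mutation count holding risk fixed
#'
#' Given the calibrated mutation rate `u`, finds the (continuous) `M` at
#' which a species' lifetime risk equals `p_target`:
#' `M = ln(p_target / C_species) / ln(u k_eff T)`. The increase over the
#' cancer's baseline, `M_add = M - M_base`, measures the tumor-suppressor
#' recruitment the species is predicted to need.
#'
#' @inheritParams calibrate_u
#' @param species The focal [species_profile()].
#' @param u Somatic mutation rate per gene per cell division (typically from
#'   [calibrate_u()]).
#' @return A list with `M_total` and `M_add`.
#' @export
solve_M <- function(cancer, species, u, mode = metabolic_mode(FALSE),
                    tab_species) {
  stopifnot(inherits(cancer, "cancer_spec"),
            inherits(species, "species_profile"))
  C_sp <- scale_C(cancer, species, tab_species)
  k_eff <- effective_k(cancer, species, mode, tab_species)
  ukT <- u * k_eff * species$T_years
  if (ukT >= 1)
    stop(sprintf("u*k*T = %.4g >= 1: risk is not decreasing in M", ukT),
         call. = FALSE)
  if (ukT <= 0) stop("u*k*T must be positive", call. = FALSE)
  M <- log(cancer$p_target / C_sp) / log(ukT)
  list(M_total = M, M_add = M - cancer$M_base)
}

#' Solve for the mutation-rate fold-reduction holding risk fixed
#'
#' The alternative adaptive route: keep `M` at the baseline and reduce `u`.
#' The required rate is `u_req = (p_target / C_species)^(1/M_base) /
#' (k_eff T)` and the fold-reduction is `u_baseline / u_req`, which is >= 1
#' for species with higher unsuppressed risk than the reference.
#'
#' @inheritParams solve_M
#' @param u_baseline The calibrated reference-species mutation rate.
#' @return A list with `u_required` and `fold`.
#' @export
solve_u_fold <- function(cancer, species, u_baseline,
                         mode = metabolic_mode(FALSE), tab_species) {
  stopifnot(inherits(cancer, "cancer_spec"),
            inherits(species, "species_profile"))
  C_sp <- scale_C(cancer, species, tab_species)
  k_eff <- effective_k(cancer, species, mode, tab_species)
  u_req <- (cancer$p_target / C_sp)^(1 / cancer$M_base) /
    (k_eff * species$T_years)
  list(u_required = u_req, fold = u_baseline / u_req)
}

#' Default cancer parameter sets
#'
#' The three cancers analysed by default, with human-tabulated stem-cell
#' counts and division rates: colorectal (C = 2e8, k = 73/yr, M = 4),
#' hepatocellular (C = 3.01e8, k = 0.9125/yr, M = 2) and esophageal
#' (C = 6,652,800, k = 33.2/yr, M = 3).
#'
#' @param p_target Lifetime risk target (default 0.001).
#' @return Named list of [cancer_spec()] objects.
#' @export
default_cancers <- function(p_target = 0.001) {
  list(
    colorectal = cancer_spec("colorectal", C_ref = 2e8, k_ref = 73,
                             M_base = 4, p_target = p_target),
    hepatocellular = cancer_spec("hepatocellular", C_ref = 3.01e8,
                                 k_ref = 0.9125, M_base = 2,
                                 p_target = p_target),
    esophageal = cancer_spec("esophageal", C_ref = 6652800, k_ref = 33.2,
                             M_base = 3, p_target = p_target))
}

#' Default species life-history profiles
#'
#' Rock hyrax (2.95 kg, 11 yr; the calibration reference), African elephant
#' (3940 kg, 65 yr), Florida manatee (467 kg, 40 yr) and human (58.7 kg,
#' 55 yr; the species whose C and k are tabulated).
#'
#' @return Named list of [species_profile()] objects.
#' @export
default_species <- function() {
  list(
    hyrax = species_profile("rock hyrax", 2.95, 11),
    elephant = species_profile("African elephant", 3940, 65),
    manatee = species_profile("Florida manatee", 467, 40),
    human = species_profile("human", 58.7, 55))
}

#' Build the full adaptive-response table
#'
#' For every cancer x species x metabolic-mode combination, calibrates `u` on
#' the reference species and solves both adaptive routes: the added driver
#' mutations `M_add` at the calibrated `u`, and the fold-reduction in `u` at
#' the baseline `M`. Reference-species cells are identities (`M_add` 0,
#' fold 1).
#'
#' @param cancers Named list of [cancer_spec()] (default [default_cancers()]).
#' @param species Named list of [species_profile()] (default
#'   [default_species()]).
#' @param modes List of [metabolic_mode()] objects (default both off and on).
#' @param reference Name (in `species`) of the calibration reference species
#'   (default `"hyrax"`).
#' @param tab_species Name of the species whose C/k are tabulated (default
#'   `"human"`).
#' @return A data frame of class `emmc_table` with one row per combination:
#'   columns `cancer`, `species`, `mr` (logical), `u_baseline`, `M_total`,
#'   `M_add`, `u_required`, `u_fold`, plus attributes recording the
#'   parameters.
#' @examples
#' tab <- build_emmc_table()
#' subset(tab, species == "African elephant" & !mr)
#' @export
build_emmc_table <- function(cancers = default_cancers(),
                             species = default_species(),
                             modes = list(metabolic_mode(FALSE),
                                          metabolic_mode(TRUE)),
                             reference = "hyrax",
                             tab_species = "human") {
  if (!reference %in% names(species))
    stop("reference species '", reference, "' not in species list",
         call. = FALSE)
  if (!tab_species %in% names(species))
    stop("tabulated species '", tab_species, "' not in species list",
         call. = FALSE)
  ref_sp <- species[[reference]]
  tab_sp <- species[[tab_species]]
  rows <- list()
  for (ca in cancers) for (mode in modes) {
    u0 <- calibrate_u(ca, ref_sp, mode, tab_species = tab_sp)
    for (sp in species) {
      cell <- tryCatch({
        m <- solve_M(ca, sp, u0, mode, tab_species = tab_sp)
        f <- solve_u_fold(ca, sp, u0, mode, tab_species = tab_sp)
        data.frame(cancer = ca$name, species = sp$name, mr = mode$enabled,
                   u_baseline = u0, M_total = m$M_total, M_add = m$M_add,
                   u_required = f$u_required, u_fold = f$fold)
      }, error = function(e) {
        stop(sprintf("cell [%s x %s, MR=%s]: %s", ca$name, sp$name,
                     mode$enabled, conditionMessage(e)), call. = FALSE)
      })
      rows[[length(rows) + 1L]] <- cell
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reference") <- ref_sp$name
  attr(out, "tab_species") <- tab_sp$name
  attr(out, "p_target") <- vapply(cancers, `[[`, numeric(1), "p_target")
  class(out) <- c("emmc_table", class(out))
  out
}

#' Read an EMMC parameter configuration
#'
#' A YAML file with top-level keys `cancers` (name -> C_ref, k_ref, M_base,
#' optional p_target) and `species` (name -> weight_kg, T_years), plus
#' optional `reference` and `tab_species` names. Missing sections fall back
#' to the packaged defaults.
#'
#' @param path Path to a YAML config file.
#' @return A list with `cancers`, `species`, `reference`, `tab_species`,
#'   suitable for `do.call(build_emmc_table, .)`.
#' @export
read_emmc_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cancers <- if (is.null(cfg$cancers)) default_cancers() else
    lapply(stats::setNames(names(cfg$cancers), names(cfg$cancers)), function(nm) {
      x <- cfg$cancers[[nm]]
      cancer_spec(nm, C_ref = x$C_ref, k_ref = x$k_ref, M_base = x$M_base,
                  p_target = if (is.null(x$p_target)) 0.001 else x$p_target)
    })
  species <- if (is.null(cfg$species)) default_species() else
    lapply(stats::setNames(names(cfg$species), names(cfg$species)), function(nm) {
      x <- cfg$species[[nm]]
      species_profile(nm, weight_kg = x$weight_kg, T_years = x$T_years)
    })
  list(cancers = cancers, species = species,
       reference = if (is.null(cfg$reference)) "hyrax" else cfg$reference,
       tab_species = if (is.null(cfg$tab_species)) "human" else cfg$tab_species)
}
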