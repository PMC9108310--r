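#' Neutral duplication-drift model of retrogene accumulation
#'
#' Neutral duplications fix at a rate equal to the duplication probability
#' `U_dup` per copy per generation, so with `n` fixed copies the family-level
#' fixation rate is `n * U_dup`: a pure-birth (Yule) process. Expected copy
#' number grows exponentially, `E[n(t)] = n0 * exp(U_dup * t)`, predicting a
#' linear relation between log copy number and time whose slope (per year,
#' divided into generations) estimates `U_dup`.
#'
#' @name duplication-drift
#' @keywords internal
NULL

#' Parameters of the duplication-drift process
#'
#' @param n0 Initial fixed copy count (integer >= 1).
#' @param U_dup Duplication-fixation probability per copy per generation
#'   (0 <= U_dup < 1, and realistically << 1).
#' @param generation_years Years per generation (> 0; default 25, the
#'   elephant value).
#' @return An object of class `drift_params`.
#' @export
drift_params <- function(n0 = 1L, U_dup = 1.1e-6, generation_years = 25) {
  if (!is.numeric(n0) || length(n0) != 1L || n0 < 1 || n0 != round(n0))
    stop("n0 must be a positive integer", call. = FALSE)
  if (!is.numeric(U_dup) || U_dup < 0 || U_dup >= 1)
    stop("U_dup must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(generation_years) || generation_years <= 0)
    stop("generation_years must be positive", call. = FALSE)
  structure(list(n0 = as.integer(n0), U_dup = U_dup,
                 generation_years = generation_years),
            class = "drift_params")
}

#' Expected copy number under neutral duplication-drift
#'
#' @param params A [drift_params()].
#' @param generations Elapsed generations (>= 0; vectorized).
#' @return `n0 * exp(U_dup * generations)`.
#' @examples
#' expected_copies(drift_params(1, 1.1e-6), 2.4e6)  # ~14 copies after 60 My
#' @export
expected_copies <- function(params, generations) {
  stopifnot(inherits(params, "drift_params"))
  if (any(generations < 0))
    stop("generations must be non-negative", call. = FALSE)
  params$n0 * exp(params$U_dup * generations)
}

#' Simulate neutral copy-number trajectories
#'
#' Discrete-generation pure-birth simulation: each generation, every one of
#' the `n` current fixed copies independently spawns a new fixed duplicate
#' with probability `U_dup` (`method = "bernoulli"`), or equivalently the
#' per-generation increment is drawn as Poisson(`n * U_dup`)
#' (`method = "poisson"`, the default; the two agree to O(U_dup^2)). Counts
#' never decrease: no loss process is modeled.
#'
#' Trajectories are recorded at generations `seq(0, horizon, by = record_every)`
#' (always including 0 and the horizon).
#'
#' @param params A [drift_params()].
#' @param horizon_generations Number of generations to simulate (>= 1).
#' @param replicates Number of independent trajectories (>= 1).
#' @param seed Integer seed; required, so no hidden global state.
#' @param method `"poisson"` (default) or `"bernoulli"`.
#' @param record_every Record interval in generations (default: horizon/50,
#'   at least 1).
#' @return A list of class `drift_sim`: `times` (generations at which counts
#'   were recorded), `counts` (replicates x times integer matrix), `params`,
#'   `method`, `seed`.
#' @export
simulate_drift <- function(params, horizon_generations, replicates = 1L,
                           seed, method = c("poisson", "bernoulli"),
                           record_every = NULL) {
  stopifnot(inherits(params, "drift_params"))
  method <- match.arg(method)
  if (missing(seed)) stop("seed must be supplied", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (horizon_generations < 1)
    stop("horizon_generations must be >= 1", call. = FALSE)
  horizon <- as.integer(horizon_generations)
  if (is.null(record_every)) record_every <- max(1L, horizon %/% 50L)
  rec <- unique(c(seq(0L, horizon, by = as.integer(record_every)), horizon))
  rec <- sort(rec)
  old <- .save_rng(seed)
  on.exit(.restore_rng(old))
  n <- rep.int(params$n0, replicates)
  counts <- matrix(0L, nrow = replicates, ncol = length(rec))
  counts[, 1L] <- n
  ri <- 2L
  for (g in seq_len(horizon)) {
    if (method == "poisson") {
      n <- n + stats::rpois(replicates, n * params$U_dup)
    } else {
      n <- n + stats::rbinom(replicates, n, params$U_dup)
    }
    if (ri <= length(rec) && g == rec[ri]) {
      counts[, ri] <- n
      ri <- ri + 1L
    }
  }
  structure(list(times = rec, counts = counts, params = params,
                 method = method, seed = seed),
            class = "drift_sim")
}

# Seed handling that restores the caller's RNG state afterwards.
.save_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Extract one trajectory from a simulation as a data frame
#'
#' @param sim A `drift_sim` from [simulate_drift()].
#' @param replicate Which replicate (default 1).
#' @param unit `"generations"` or `"years"` for the time column (years uses
#'   `generation_years` from the parameters).
#' @return A data frame with columns `time` and `copies`, of class
#'   `copy_trajectory`; the time unit is stored in attribute `unit`.
#' @export
drift_trajectory <- function(sim, replicate = 1L,
                             unit = c("generations", "years")) {
  stopifnot(inherits(sim, "drift_sim"))
  unit <- match.arg(unit)
  tm <- sim$times
  if (unit == "years") tm <- tm * sim$params$generation_years
  out <- data.frame(time = tm, copies = sim$counts[replicate, ])
  attr(out, "unit") <- unit
  class(out) <- c("copy_trajectory", class(out))
  out
}

#' Build a copy-number trajectory from raw vectors
#'
#' @param time Strictly increasing times.
#' @param copies Positive integer copy counts.
#' @param unit `"years"` (default) or `"generations"`.
#' @return A `copy_trajectory` data frame.
#' @export
copy_trajectory <- function(time, copies, unit = c("years", "generations")) {
  unit <- match.arg(unit)
  if (length(time) != length(copies))
    stop("time and copies must have equal length", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(copies < 1) || any(copies != round(copies)))
    stop("copies must be positive integers", call. = FALSE)
  out <- data.frame(time = time, copies = as.integer(copies))
  attr(out, "unit") <- unit
  class(out) <- c("copy_trajectory", class(out))
  out
}

#' Fit the log-linear accumulation slope
#'
#' Ordinary least squares of the natural log of copy number against time.
#' Under the neutral model the slope equals `U_dup` per generation (or
#' `U_dup / generation_years` per year when times are in years).
#'
#' @param traj A `copy_trajectory` (or data frame with `time`, `copies`).
#' @return An object of class `slope_fit`: `slope`, `intercept`, `se`,
#'   `n_points`, `unit`.
#' @examples
#' tr <- copy_trajectory(c(0, 6e7), c(1, 19))
#' fit_log_slope(tr)$slope  # ln(19)/6e7 ~ 4.9e-8 per year
#' @export
fit_log_slope <- function(traj) {
  if (!all(c("time", "copies") %in% names(traj)))
    stop("trajectory must have 'time' and 'copies' columns", call. = FALSE)
  if (length(unique(traj$time)) < 2L)
    stop("need at least 2 distinct time points", call. = FALSE)
  if (any(traj$copies < 1))
    stop("copy counts must be >= 1 to take logs", call. = FALSE)
  fit <- stats::lm(log(copies) ~ time, data = traj)
  # summary.lm warns on an exactly exponential (zero-residual) input, which
  # is a legitimate use here (two-point and noise-free trajectories)
  co <- suppressWarnings(summary(fit))$coefficients
  se <- if (nrow(traj) > 2L) co["time", "Std. Error"] else NA_real_
  structure(list(slope = unname(co["time", "Estimate"]),
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 se = se, n_points = nrow(traj),
                 unit = attr(traj, "unit", exact = TRUE)),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("<slope_fit> slope=%.4g per %s (se %.3g, n=%d)\n",
              x$slope, if (is.null(x$unit)) "time unit" else sub("s$", "", x$unit),
              x$se, x$n_points))
  invisible(x)
}

#' Estimate the per-generation duplication rate
#'
#' Converts a per-year log-accumulation slope into a per-generation
#' duplication-fixation probability: `U_dup = slope * generation_years`.
#'
#' @param slope_per_year Log-linear slope in per-year units (> 0), e.g. from
#'   [fit_log_slope()] on a trajectory in years.
#' @param generation_years Years per generation (> 0).
#' @return Estimated `U_dup` per generation.
#' @examples
#' estimate_Udup(4.6e-8, 25)  # ~1.15e-6
#' @export
estimate_Udup <- function(slope_per_year, generation_years) {
  if (!is.numeric(slope_per_year) || slope_per_year <= 0)
    stop("slope_per_year must be positive", call. = FALSE)
  if (!is.numeric(generation_years) || generation_years <= 0)
    stop("generation_years must be positive", call. = FALSE)
  slope_per_year * generation_years
}

#' Simulate a duplication genealogy
#'
#' Grows a pure-birth genealogy from one copy to `target_copies` using exact
#' Yule waiting times: from `i` copies, the wait to the next fixation is
#' exponential with rate `i * U_dup` per generation, and the duplicating copy
#' is chosen uniformly. Tips are labeled `RTG1..RTGn` in birth order; branch
#' lengths are in generations. The tree is an [ape::phylo] object and can be
#' written with [ape::write.tree].
#'
#' @param params A [drift_params()] with `U_dup > 0`.
#' @param target_copies Number of tips (>= 1).
#' @param seed Integer seed.
#' @param horizon_generations Optional time (generations) to which tips are
#'   extended past the last duplication; default `NULL` stops the tree at the
#'   final birth.
#' @return A list of class `duplication_genealogy`: `tree` (phylo; `NULL`
#'   when `target_copies` is 1), `birth_times` (generations of each
#'   fixation), `params`, `seed`.
#' @export
simulate_genealogy <- function(params, target_copies, seed,
                               horizon_generations = NULL) {
  stopifnot(inherits(params, "drift_params"))
  if (missing(seed)) stop("seed must be supplied", call. = FALSE)
  if (target_copies < 1)
    stop("target_copies must be >= 1", call. = FALSE)
  if (params$U_dup <= 0 && target_copies > params$n0)
    stop("target unreachable: U_dup = 0 cannot add copies", call. = FALSE)
  old <- .save_rng(seed)
  on.exit(.restore_rng(old))
  n_target <- as.integer(target_copies)
  # waiting times between fixations i -> i+1: Exp(rate = i * U_dup)
  births <- c(0, if (n_target > 1L)
    cumsum(stats::rexp(n_target - 1L, rate = seq_len(n_target - 1L) * params$U_dup)))
  tree <- NULL
  if (n_target > 1L) {
    # Node ids: tips 1..n (RTG1..RTGn in birth order), internal node n+k
    # created at the k-th duplication, time births[k+1]; root is n+1.
    # Each open lineage hangs from the internal node under which it arose;
    # edges are closed when the lineage duplicates, or at the final time.
    open_parent <- c(0L)     # 0 = above the root (no edge emitted)
    open_tip <- c(1L)
    parent <- integer(0); child <- integer(0)
    for (k in seq_len(n_target - 1L)) {
      dup <- sample.int(k, 1L)
      v <- n_target + k
      if (open_parent[dup] > 0L) {          # close the duplicating edge
        parent <- c(parent, open_parent[dup])
        child <- c(child, v)
      }
      new_tip <- k + 1L
      open_parent <- c(open_parent[-dup], v, v)
      open_tip <- c(open_tip[-dup], open_tip[dup], new_tip)
    }
    parent <- c(parent, open_parent)        # pendant edges to the tips
    child <- c(child, open_tip)
    t_end <- births[n_target]
    if (!is.null(horizon_generations)) {
      if (horizon_generations < t_end)
        stop("horizon_generations precedes the last duplication", call. = FALSE)
      t_end <- horizon_generations
    }
    node_time <- c(rep(t_end, n_target), births[2:n_target])
    tree <- list(edge = cbind(parent, child),
                 edge.length = node_time[child] - node_time[parent],
                 Nnode = n_target - 1L,
                 tip.label = paste0("RTG", seq_len(n_target)))
    class(tree) <- "phylo"
    tree <- ape::reorder.phylo(tree, "cladewise")
  }
  structure(list(tree = tree, birth_times = births, params = params,
                 seed = seed),
            class = "duplication_genealogy")
}

#' Read / write copy-number trajectories as TSV
#'
#' Two tab-separated columns, `time` and `copies`, with the time unit in a
#' `# unit:` comment header.
#'
#' @param traj A `copy_trajectory`.
#' @param path File path.
#' @return `read_trajectory` returns a `copy_trajectory`;
#'   `write_trajectory` returns `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  unit <- attr(traj, "unit", exact = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unit: %s", if (is.null(unit)) "years" else unit), con)
  utils::write.table(traj[, c("time", "copies")], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  first <- readLines(path, n = 1L)
  unit <- if (grepl("^# unit:", first))
    trimws(sub("^# unit:", "", first)) else "years"
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  copy_trajectory(df$time, df$copies, unit = match.arg(unit, c("years", "generations")))
}
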