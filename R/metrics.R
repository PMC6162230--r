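#' Measure population observables of a world
#'
#' Exact population averages: the effective cooperation rate
#' \eqn{\epsilon = (1 - s)(1 - \alpha)}, the mean abstention probability,
#' the strategy fractions, and the occupancy fraction of every abstention
#' level. A pure function of the world: it never perturbs the dynamics or
#' the RNG stream.
#'
#' @param world A populated `lattice_world`.
#' @param step Monte Carlo step index to record alongside the observables.
#' @return A one-row tibble with columns `step`, `mean_eps`, `mean_alpha`,
#'   `frac_coop`, `frac_defect`, and one occupancy column per abstention
#'   level (`alpha_0`, `alpha_0.125`, ...).
#' @export
measure_state <- function(world, step = NA_integer_) {
  assert_populated(world)
  n <- n_agents(world)
  alpha <- world$grid$levels[world$alpha_idx + 1L]
  s <- as.integer(world$s)
  hist <- tabulate(world$alpha_idx + 1L, nbins = length(world$grid$levels)) / n
  out <- c(
    list(step = step,
         mean_eps = mean((1 - s) * (1 - alpha)),
         mean_alpha = mean(alpha),
         frac_coop = mean(s == 0L),
         frac_defect = mean(s == 1L)),
    as.list(stats::setNames(hist, alpha_level_names(world$grid)))
  )
  tibble::as_tibble(out)
}

#' Count occupied abstention levels
#'
#' Number of abstention levels whose occupancy fraction is at least
#' `min_fraction` (strictly positive when `min_fraction = 0`). The default
#' 1\% threshold filters single-agent relics when asking how many levels the
#' population has converged to.
#'
#' @param metrics A metrics row from [measure_state()] or one row of a run's
#'   `time_series`.
#' @param min_fraction Occupancy threshold in `[0, 1)`.
#' @return Integer count of occupied levels.
#' @export
distinct_alpha_levels <- function(metrics, min_fraction = 0.01) {
  stopifnot(min_fraction >= 0, min_fraction < 1)
  occ <- unlist(metrics[grep("^alpha_", names(metrics))])
  if (min_fraction == 0) sum(occ > 0) else sum(occ >= min_fraction)
}

#' Average an ensemble of runs
#'
#' Combines independent runs that share a configuration (apart from the
#' seed) into per-step ensemble means and standard errors, plus a
#' stationary-state summary taken from each run's final recorded state.
#' Standard errors are computed across runs, not across lattice sites, since
#' sites are correlated by spatial clustering while runs are independent.
#'
#' @param results A list of `pdpa_run` objects from [run_simulation()].
#' @return An object of class `pdpa_ensemble`: a list with
#'   \describe{
#'     \item{time_series}{tibble of per-step ensemble means (same column
#'       names as a single run) plus an `<name>_se` column per field;}
#'     \item{stationary}{tibble with one row per run: the final recorded
#'       metrics and the run's seed;}
#'     \item{n_runs}{ensemble size.}
#'   }
#' @export
ensemble_average <- function(results) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1), "pdpa_run")))
  cfgs <- lapply(results, function(r) {
    c <- r$config
    c$seed <- NULL
    c
  })
  if (!all(vapply(cfgs, identical, logical(1), cfgs[[1L]]))) {
    stop("cannot aggregate: runs differ in more than the seed", call. = FALSE)
  }
  steps <- lapply(results, function(r) r$time_series$step)
  if (!all(vapply(steps, identical, logical(1), steps[[1L]]))) {
    stop("cannot aggregate: runs recorded different step grids", call. = FALSE)
  }
  k <- length(results)
  fields <- setdiff(names(results[[1L]]$time_series), "step")
  arr <- vapply(results, function(r) as.matrix(r$time_series[fields]),
                matrix(0, nrow(results[[1L]]$time_series), length(fields)))
  mean_mat <- apply(arr, c(1, 2), mean)
  se_mat <- if (k > 1) apply(arr, c(1, 2), sd) / sqrt(k) else mean_mat * 0
  ts <- tibble::as_tibble(cbind(
    data.frame(step = steps[[1L]]),
    as.data.frame(mean_mat),
    stats::setNames(as.data.frame(se_mat), paste0(fields, "_se"))
  ))
  stationary <- do.call(rbind, lapply(results, function(r) {
    row <- r$time_series[nrow(r$time_series), ]
    row$seed <- r$config$seed
    row
  }))
  structure(
    list(time_series = ts, stationary = tibble::as_tibble(stationary),
         n_runs = k),
    class = "pdpa_ensemble"
  )
}

#' Summarize an ensemble's stationary state
#'
#' Ensemble mean and standard error (across runs) of the stationary
#' observables, plus the modal count of abstention levels with occupancy at
#' least `min_fraction` in the final state.
#'
#' @param ens A `pdpa_ensemble` from [ensemble_average()].
#' @param min_fraction Occupancy threshold passed to
#'   [distinct_alpha_levels()].
#' @return A one-row tibble with `mean_eps`, `mean_alpha`, `frac_coop`, their
#'   standard errors, `modal_alpha_levels`, and `n_runs`.
#' @export
stationary_summary <- function(ens, min_fraction = 0.01) {
  stopifnot(inherits(ens, "pdpa_ensemble"))
  st <- ens$stationary
  k <- ens$n_runs
  se <- function(x) if (k > 1) sd(x) / sqrt(k) else 0
  counts <- vapply(seq_len(nrow(st)), function(i) {
    distinct_alpha_levels(st[i, ], min_fraction)
  }, numeric(1))
  tab <- table(counts)
  tibble::tibble(
    mean_eps = mean(st$mean_eps), se_eps = se(st$mean_eps),
    mean_alpha = mean(st$mean_alpha), se_alpha = se(st$mean_alpha),
    frac_coop = mean(st$frac_coop), se_coop = se(st$frac_coop),
    modal_alpha_levels = as.numeric(names(tab)[which.max(tab)]),
    n_runs = k
  )
}

#' @export
print.pdpa_ensemble <- function(x, ...) {
  cat(sprintf("pdpa_ensemble: %d runs, %d recorded steps\n",
              x$n_runs, nrow(x$time_series)))
  print(stationary_summary(x))
  invisible(x)
}
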