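#' Preset configurations for the standard experiment designs
#'
#' `scale = "paper"` reproduces the published protocol: a 102 x 102 lattice,
#' 1e5 Monte Carlo steps and 100-run ensembles, with R = 1, P = 0, S = 0,
#' L = 0.4. `scale = "desk"` is a reduced protocol (60 x 60, 2e4 steps,
#' 20 runs) sized so that property checks complete in minutes while leaving
#' the qualitative behaviour intact.
#'
#' @param game `"pd"`, `"opd"`, or `"pdpa"` — the initialization mode.
#' @param scheme `"synchronous"` or `"asynchronous"`.
#' @param scale `"paper"` or `"desk"`.
#' @param T Temptation to defect. Default 1.4.
#' @param seed Base seed; ensemble run `i` uses `seed + i - 1`.
#' @param ... Further overrides passed to [simulation_config()].
#' @return A [simulation_config()] carrying the recommended ensemble size in
#'   `attr(, "runs")`.
#' @export
preset_config <- function(game = c("pdpa", "pd", "opd"),
                          scheme = c("synchronous", "asynchronous"),
                          scale = c("desk", "paper"),
                          T = 1.4, seed = 1L, ...) {
  game <- match.arg(game)
  scheme <- match.arg(scheme)
  scale <- match.arg(scale)
  dims <- switch(scale,
    paper = list(side = 102L, mc_steps = 100000L, runs = 100L),
    desk = list(side = 60L, mc_steps = 20000L, runs = 20L)
  )
  cfg <- simulation_config(
    params = game_params(T = T, L = 0.4),
    side = dims$side,
    update_scheme = scheme,
    init_mode = game,
    mc_steps = dims$mc_steps,
    seed = seed,
    record_every = max(1L, dims$mc_steps %/% 400L),
    ...
  )
  attr(cfg, "runs") <- dims$runs
  cfg
}

#' Run an ensemble of independent simulations
#'
#' Run `i` (for `i = 1, ..., runs`) uses seed `config$seed + i - 1`;
#' otherwise all runs share `config`.
#'
#' @param config A [simulation_config()].
#' @param runs Ensemble size; defaults to the preset's recommendation, or 20.
#' @return A `pdpa_ensemble` (see [ensemble_average()]).
#' @export
run_ensemble <- function(config, runs = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(runs)) runs <- attr(config, "runs")
  if (is.null(runs)) runs <- 20L
  runs <- as.integer(runs)
  stopifnot(runs >= 1L)
  results <- lapply(seq_len(runs) - 1L, function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    attr(cfg, "runs") <- NULL
    run_simulation(cfg)
  })
  ensemble_average(results)
}

#' Specification of a parameter sweep
#'
#' All cells share the lattice, step count, scheme(s) and initialization
#' mode(s) of `base_config`; only the payoffs and the seeds vary. Seeds are
#' a pure function of the (T, game, scheme) combination and the run index
#' (`base seed + (block - 1) * runs + run - 1`), so sweep outputs are
#' invariant to cell execution order; cells that differ only in the loner's
#' payoff L share their seeds, giving paired comparisons across L.
#'
#' @param T_values Temptation values to sweep.
#' @param L_values Loner's-payoff values to sweep (a single value for a
#'   temptation sweep).
#' @param runs Ensemble size per cell.
#' @param base_config A [simulation_config()] template.
#' @param games Initialization modes to cross with the grid; defaults to the
#'   template's mode.
#' @param schemes Updating schemes to cross; defaults to the template's.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(T_values, L_values, runs, base_config,
                       games = base_config$init_mode,
                       schemes = base_config$update_scheme) {
  stopifnot(inherits(base_config, "simulation_config"))
  stopifnot(all(games %in% c("pd", "opd", "pdpa")),
            all(schemes %in% c("synchronous", "asynchronous")))
  structure(
    list(T_values = as.numeric(T_values), L_values = as.numeric(L_values),
         runs = as.integer(runs), base_config = base_config,
         games = games, schemes = schemes),
    class = "sweep_spec"
  )
}

sweep_cells <- function(spec) {
  cells <- expand.grid(T = spec$T_values, L = spec$L_values,
                       game = spec$games, scheme = spec$schemes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # the seed block is a pure function of the (T, game, scheme) combination
  # and the run index; L does not enter it, so cells that differ only in L
  # share their seeds (paired comparisons, and pd-mode results are exactly
  # invariant to L)
  key <- interaction(cells$T, cells$game, cells$scheme, drop = TRUE)
  cells$seed_block <- as.integer(factor(key, levels = unique(key)))
  cells
}

run_one_cell <- function(spec, cell) {
  base <- spec$base_config
  cfg <- simulation_config(
    params = game_params(T = cell$T, L = cell$L,
                         R = base$params$R, P = base$params$P,
                         S = base$params$S, K = base$params$K,
                         strict = base$params$strict),
    side = base$side,
    update_scheme = cell$scheme,
    init_mode = cell$game,
    mc_steps = base$mc_steps,
    seed = base$seed + (cell$seed_block - 1L) * spec$runs,
    record_every = base$record_every,
    grid = base$grid,
    stop_when_absorbing = base$stop_when_absorbing
  )
  ens <- run_ensemble(cfg, spec$runs)
  cbind(
    tibble::tibble(game = cell$game, scheme = cell$scheme,
                   T = cell$T, L = cell$L),
    stationary_summary(ens)
  )
}

#' Temptation sweep: stationary observables versus T
#'
#' For every combination of game, scheme and temptation value, runs an
#' ensemble and reports the stationary ensemble means of the effective
#' cooperation rate and the abstention probability, with standard errors.
#'
#' @param spec A [sweep_spec()] with a single loner's-payoff value.
#' @param progress Print one line per completed cell.
#' @return A tibble with one row per (game, scheme, T) cell.
#' @export
run_T_sweep <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (length(spec$T_values) == 0L) {
    stop("sweep spec has an empty temptation grid", call. = FALSE)
  }
  if (length(spec$L_values) != 1L) {
    stop("a temptation sweep needs a single loner's payoff L", call. = FALSE)
  }
  cells <- sweep_cells(spec)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    out <- run_one_cell(spec, cells[i, ])
    if (progress) {
      message(sprintf("[%d/%d] %s/%s T=%g: eps=%.3f alpha=%.3f",
                      i, nrow(cells), cells$game[i], cells$scheme[i],
                      cells$T[i], out$mean_eps, out$mean_alpha))
    }
    out
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Temptation--loner's-payoff plane
#'
#' Runs an ensemble for every cell of the T x L grid and reports stationary
#' ensemble means, one row per cell — the tidy-table form of the usual
#' heat map (rendering is left to the caller).
#'
#' In strict mode (set on the template's parameters) every cell must satisfy
#' the dilemma bounds `1 < T < 2`, `0 < L < 1`.
#'
#' @inheritParams run_T_sweep
#' @return A tibble with one row per (game, scheme, T, L) cell.
#' @export
run_TL_heatmap <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (length(spec$T_values) == 0L || length(spec$L_values) == 0L) {
    stop("sweep spec has an empty T or L grid", call. = FALSE)
  }
  cells <- sweep_cells(spec)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    out <- run_one_cell(spec, cells[i, ])
    if (progress) {
      message(sprintf("[%d/%d] %s/%s T=%g L=%g: eps=%.3f alpha=%.3f",
                      i, nrow(cells), cells$game[i], cells$scheme[i],
                      cells$T[i], cells$L[i], out$mean_eps, out$mean_alpha))
    }
    out
  })
  tibble::as_tibble(do.call(rbind, rows))
}
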