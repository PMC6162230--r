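#' Simulation configuration
#'
#' Collects everything needed to reproduce a run: game parameters, lattice
#' side, abstention grid, updating scheme, initialization mode, Monte Carlo
#' step count, seed, and the time-series sampling interval.
#'
#' One Monte Carlo (MC) step means: under synchronous updating, one full
#' payoff-accrual pass over all edges followed by one simultaneous imitation
#' pass; under asynchronous updating, `N = side^2` elementary moves with the
#' focal agent drawn uniformly with replacement (each agent acts once on
#' average).
#'
#' @param params A [game_params()] object.
#' @param side Lattice side length.
#' @param update_scheme `"synchronous"` or `"asynchronous"`.
#' @param init_mode `"pd"` (all agents never abstain), `"opd"` (each agent
#'   abstains always or never, with equal probability), or `"pdpa"`
#'   (abstention level uniform over the whole grid).
#' @param mc_steps Number of Monte Carlo steps; at least 1.
#' @param seed Integer RNG seed; every source of randomness in the run flows
#'   from it.
#' @param record_every Sampling interval of the recorded time series (the
#'   initial and final states are always recorded).
#' @param grid An [alpha_grid()]; defaults to the von Neumann grid
#'   (`kappa = 4`, nine levels).
#' @param stop_when_absorbing Stop early once the state can no longer change
#'   (homogeneous strategy and abstention level; under asynchronous updating
#'   also a population that always abstains). Off by default to mirror the
#'   fixed-length protocol.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(params = game_params(),
                              side = 102L,
                              update_scheme = c("synchronous", "asynchronous"),
                              init_mode = c("pdpa", "pd", "opd"),
                              mc_steps = 1e5L,
                              seed = 1L,
                              record_every = 100L,
                              grid = alpha_grid(4),
                              stop_when_absorbing = FALSE) {
  update_scheme <- match.arg(update_scheme)
  init_mode <- match.arg(init_mode)
  stopifnot(inherits(params, "game_params"), inherits(grid, "alpha_grid"))
  mc_steps <- as.integer(mc_steps)
  record_every <- as.integer(record_every)
  seed <- as.integer(seed)
  if (is.na(mc_steps) || mc_steps < 1L) {
    stop("mc_steps must be at least 1", call. = FALSE)
  }
  if (is.na(record_every) || record_every < 1L) {
    stop("record_every must be at least 1", call. = FALSE)
  }
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  side <- as.integer(side)
  if (is.na(side) || side < 2L) {
    stop("degenerate lattice: side must be at least 2", call. = FALSE)
  }
  structure(
    list(params = params, side = side, update_scheme = update_scheme,
         init_mode = init_mode, mc_steps = mc_steps, seed = seed,
         record_every = record_every, grid = grid,
         stop_when_absorbing = stop_when_absorbing),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "simulation_config: %s/%s, %d x %d, %d MC steps, seed %d\n",
    x$init_mode, x$update_scheme, x$side, x$side, x$mc_steps, x$seed))
  print(x$params)
  invisible(x)
}

#' Initialize the population
#'
#' Every agent receives a strategy, cooperate or defect with equal
#' probability, independently. The abstention level depends on the mode:
#' `"pd"` puts all agents at level 0 (never abstain, recovering the classic
#' prisoner's dilemma), `"opd"` assigns level 0 or level 1 with equal
#' probability (recovering the optional prisoner's dilemma), and `"pdpa"`
#' draws uniformly over all grid levels.
#'
#' Consumes R's RNG stream: first all strategies (column-major site order),
#' then all abstention levels.
#'
#' @param world An unpopulated (or to-be-overwritten) [build_lattice()] world.
#' @param mode `"pd"`, `"opd"`, or `"pdpa"`.
#' @return The populated world.
#' @export
init_population <- function(world, mode = c("pdpa", "pd", "opd")) {
  stopifnot(inherits(world, "lattice_world"))
  mode <- match.arg(mode)
  n <- n_agents(world)
  nlev <- length(world$grid$levels)
  world$s <- matrix(sample(0:1, n, replace = TRUE), world$side, world$side)
  idx <- switch(mode,
    pd = rep(0L, n),
    opd = sample(c(0L, nlev - 1L), n, replace = TRUE),
    pdpa = sample(0:(nlev - 1L), n, replace = TRUE)
  )
  world$alpha_idx <- matrix(idx, world$side, world$side)
  world
}

#' Synchronous payoff accrual
#'
#' Every undirected lattice edge is resolved exactly once: one abstention
#' draw per endpoint, then the pairwise payoffs; both endpoints' utilities
#' receive their respective payoffs. Each agent's utility is the sum over its
#' four incident edges, so it lies in `[4 * min(P, S), 4 * max(T, R, L)]`.
#'
#' Edge order (which fixes the RNG stream): sites in column-major linear
#' order, each resolving its South then East edge, drawing the owner's
#' abstention before the neighbour's.
#'
#' @param world A populated `lattice_world`.
#' @param params A [game_params()] object.
#' @return Numeric `side x side` matrix of per-agent utilities.
#' @export
accrue_payoffs_sync <- function(world, params) {
  assert_populated(world)
  engine_accrue_sync(world$s, world$alpha_idx, world$grid$levels,
                     params$T, params$L, params$R, params$P, params$S)
}

#' Synchronous best-neighbour imitation
#'
#' All agents update simultaneously from the same utility ledger. An agent
#' adopts the strategy and abstention level of its best neighbour only when
#' that neighbour's utility strictly exceeds both the agent's own utility and
#' every other neighbour's. Any tie for the neighbourhood maximum, or the
#' agent itself being (weakly) best, leaves the agent unchanged. Utilities
#' are compared with absolute tolerance `1e-9`.
#'
#' @param world A populated `lattice_world` (the state the ledger was
#'   computed from).
#' @param ledger Utility matrix from [accrue_payoffs_sync()].
#' @return The updated world. Consumes no randomness.
#' @export
imitation_update_sync <- function(world, ledger) {
  assert_populated(world)
  stopifnot(is.matrix(ledger), all(dim(ledger) == dim(world$s)))
  res <- engine_imitate_sync(world$s, world$alpha_idx, ledger)
  world$s <- res$s
  world$alpha_idx <- res$alpha_idx
  world
}

#' One synchronous Monte Carlo step
#'
#' Composition of [accrue_payoffs_sync()] and [imitation_update_sync()]:
#' payoffs always reflect the pre-update states.
#'
#' @inheritParams accrue_payoffs_sync
#' @return The updated world.
#' @export
sync_step <- function(world, params) {
  imitation_update_sync(world, accrue_payoffs_sync(world, params))
}

#' Fermi imitation probability
#'
#' The probability that an agent with utility `ux` copies a partner with
#' utility `uy`:
#' \deqn{W = \left(1 + \exp[(u_x - u_y)/(\kappa K)]\right)^{-1}}
#' where `kappa` is the agent degree and `K > 0` the noise amplitude.
#' Evaluated in a numerically stable form; for large utility deficits W
#' approaches 1 without overflow.
#'
#' @param ux,uy Utilities of the focal agent and of the partner.
#' @param kappa Agent degree (4 on the von Neumann lattice).
#' @param K Noise amplitude; must be positive.
#' @return Probability in (0, 1).
#' @examples
#' fermi_probability(1, 1, 4, 0.1)          # equal utilities: 0.5
#' fermi_probability(0.4 * log(3), 0, 4, 0.1) # 0.25
#' @export
fermi_probability <- function(ux, uy, kappa = 4, K = 0.1) {
  stopifnot(K > 0, kappa >= 1)
  mapply(engine_fermi, ux, uy, MoreArgs = list(kappa = kappa, K = K))
}

#' One asynchronous elementary move
#'
#' Picks a focal agent x uniformly at random (or uses `site` when given, a
#' testing hook that skips the site draw), computes its utility from fresh
#' abstention-drawn interactions with all four neighbours, picks one
#' neighbour y uniformly, computes y's utility likewise from y's four
#' interactions (the shared x-y edge is drawn independently for each
#' utility), and, if `u_y > u_x`, lets x copy y's strategy and abstention
#' level with the Fermi probability [fermi_probability()]. The adoption
#' applies immediately.
#'
#' @param world A populated `lattice_world`.
#' @param params A [game_params()] object.
#' @param site Optional focal site, `c(row, col)`; `NULL` (default) draws it
#'   uniformly.
#' @return The world, possibly mutated at one site, with attribute `"copied"`
#'   saying whether an adoption happened.
#' @export
async_elementary_move <- function(world, params, site = NULL) {
  assert_populated(world)
  if (is.null(site)) {
    lin <- -1L
  } else {
    site <- as.integer(site)
    stopifnot(length(site) == 2L, all(site >= 1L), all(site <= world$side))
    lin <- (site[2L] - 1L) * world$side + (site[1L] - 1L)
  }
  res <- engine_async_move(world$s, world$alpha_idx, world$grid$levels,
                           params$T, params$L, params$R, params$P, params$S,
                           params$K, lin)
  world$s <- res$s
  world$alpha_idx <- res$alpha_idx
  attr(world, "copied") <- res$copied
  world
}

#' One asynchronous Monte Carlo step
#'
#' Performs exactly `N = side^2` elementary moves with the focal agent drawn
#' uniformly with replacement, so each agent acts once on average.
#'
#' @inheritParams async_elementary_move
#' @return The updated world.
#' @export
async_step <- function(world, params) {
  assert_populated(world)
  res <- engine_async_step(world$s, world$alpha_idx, world$grid$levels,
                           params$T, params$L, params$R, params$P, params$S,
                           params$K)
  world$s <- res$s
  world$alpha_idx <- res$alpha_idx
  world
}

#' Run one seeded simulation
#'
#' Seeds R's RNG from `config$seed`, initializes the population, iterates
#' the selected step operator `config$mc_steps` times, and records population
#' metrics at step 0, every `config$record_every` steps, and at the final
#' step. Two runs with the same configuration produce identical results.
#'
#' @param config A [simulation_config()].
#' @return An object of class `pdpa_run`: a list with
#'   \describe{
#'     \item{config}{the configuration used;}
#'     \item{time_series}{a tibble with columns `step`, `mean_eps`,
#'       `mean_alpha`, `frac_coop`, `frac_defect`, and one occupancy column
#'       per abstention level (`alpha_0`, `alpha_0.125`, ...);}
#'     \item{final_world}{the `lattice_world` after the last executed step;}
#'     \item{steps_run}{number of steps actually executed (less than
#'       `mc_steps` only with `stop_when_absorbing`).}
#'   }
#' @examples
#' cfg <- simulation_config(side = 20, mc_steps = 50, seed = 42,
#'                          record_every = 10)
#' run <- run_simulation(cfg)
#' head(run$time_series)
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  world <- build_lattice(config$side, config$grid)
  world <- init_population(world, config$init_mode)
  p <- config$params
  res <- engine_run(world$s, world$alpha_idx, world$grid$levels,
                    p$T, p$L, p$R, p$P, p$S, p$K,
                    config$update_scheme == "synchronous",
                    config$mc_steps, config$record_every,
                    config$stop_when_absorbing)
  world$s <- res$s
  world$alpha_idx <- res$alpha_idx
  ts <- as.data.frame(res$metrics)
  names(ts) <- c("step", "mean_eps", "mean_alpha", "frac_coop", "frac_defect",
                 alpha_level_names(config$grid))
  structure(
    list(config = config, time_series = tibble::as_tibble(ts),
         final_world = world, steps_run = res$steps_run),
    class = "pdpa_run"
  )
}

alpha_level_names <- function(grid) {
  paste0("alpha_", vapply(grid$levels, format, character(1)))
}

#' @export
print.pdpa_run <- function(x, ...) {
  cat(sprintf("pdpa_run: %s/%s, %d x %d, %d steps run (seed %d)\n",
              x$config$init_mode, x$config$update_scheme, x$config$side,
              x$config$side, x$steps_run, x$config$seed))
  last <- x$time_series[nrow(x$time_series), ]
  cat(sprintf("  final: mean eps = %.4f, mean alpha = %.4f, frac C = %.4f\n",
              last$mean_eps, last$mean_alpha, last$frac_coop))
  invisible(x)
}
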