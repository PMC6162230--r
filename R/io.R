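#' Write a run's time series to CSV
#'
#' Schema: `step`, `mean_eps`, `mean_alpha`, `frac_coop`, then one occupancy
#' column per abstention level (`alpha_0`, `alpha_0.125`, ...).
#'
#' @param run A `pdpa_run` or `pdpa_ensemble` (means are written for an
#'   ensemble).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(run, path) {
  ts <- if (inherits(run, "pdpa_ensemble")) run$time_series else run$time_series
  keep <- c("step", "mean_eps", "mean_alpha", "frac_coop",
            grep("^alpha_", names(ts), value = TRUE))
  keep <- keep[!grepl("_se$", keep)]
  write.csv(ts[keep], path, row.names = FALSE)
  invisible(path)
}

#' Write a lattice snapshot as plain text
#'
#' One line per lattice row; per-cell token `s:alpha_index` where `s` is the
#' strategy (0 = C, 1 = D) and `alpha_index` the 0-based index into the
#' abstention grid. A header comment line records the side length and the
#' degree so the file round-trips through [read_snapshot()].
#'
#' @param world A populated `lattice_world`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(world, path) {
  assert_populated(world)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pdpa snapshot side=%d kappa=%d",
                     world$side, world$grid$kappa), con)
  for (r in seq_len(world$side)) {
    writeLines(paste(sprintf("%d:%d", world$s[r, ], world$alpha_idx[r, ]),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read a lattice snapshot written by [write_snapshot()]
#'
#' @param path Snapshot file path.
#' @return A populated `lattice_world`.
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path)
  header <- lines[1L]
  m <- regmatches(header, regexec("side=(\\d+) kappa=(\\d+)", header))[[1L]]
  if (length(m) != 3L) stop("not a pdpa snapshot file: ", path, call. = FALSE)
  side <- as.integer(m[2L])
  kappa <- as.integer(m[3L])
  body <- lines[-1L]
  stopifnot(length(body) == side)
  s <- matrix(NA_integer_, side, side)
  a <- matrix(NA_integer_, side, side)
  for (r in seq_len(side)) {
    toks <- strsplit(strsplit(body[r], " ", fixed = TRUE)[[1L]], ":",
                     fixed = TRUE)
    stopifnot(length(toks) == side)
    s[r, ] <- as.integer(vapply(toks, `[`, character(1), 1L))
    a[r, ] <- as.integer(vapply(toks, `[`, character(1), 2L))
  }
  world_from_matrices(s, a, alpha_grid(kappa))
}

#' Write a reproducibility manifest
#'
#' Records the full configuration, the seed, and the package version as
#' JSON — enough to reproduce a run's outputs bit-for-bit.
#'
#' @param config A [simulation_config()] (or a list of them for sweeps).
#' @param path Output JSON path.
#' @param extra Optional named list of additional fields (e.g. sweep grids).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, extra = list()) {
  describe <- function(cfg) {
    list(params = cfg$params[c("T", "L", "R", "P", "S", "K")],
         side = cfg$side, update_scheme = cfg$update_scheme,
         init_mode = cfg$init_mode, mc_steps = cfg$mc_steps,
         seed = cfg$seed, record_every = cfg$record_every,
         kappa = cfg$grid$kappa,
         stop_when_absorbing = cfg$stop_when_absorbing)
  }
  manifest <- c(
    list(package = "pdpa",
         version = as.character(utils::packageVersion("pdpa")),
         config = describe(config)),
    extra
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
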