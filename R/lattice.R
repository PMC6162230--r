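#' Build a toroidal square lattice
#'
#' Creates an unpopulated `side` x `side` world with periodic boundary
#' conditions (a toroid) and von Neumann adjacency: every site has exactly
#' four neighbours (up, down, left, right), wrapping around at the edges.
#' Coordinates are 1-based `(row, column)` pairs, matching R matrix indexing;
#' sites also have a linear index in column-major order.
#'
#' `side = 2` is a degenerate torus on which the up and down (and left and
#' right) neighbours of a site coincide; each such neighbour then counts with
#' multiplicity two. It is permitted only with `strict = FALSE` and is meant
#' for hand-checkable tests, not for production runs.
#'
#' @param side Lattice side length; the population holds `side^2` agents.
#' @param grid An [alpha_grid()] giving the admissible abstention levels.
#' @param strict If `TRUE`, `side < 3` is an error; default allows `side = 2`.
#' @return An object of class `lattice_world` with fields `side`, `grid`, and
#'   unpopulated state matrices `s` (strategy 0/1) and `alpha_idx` (0-based
#'   index into `grid$levels`).
#' @examples
#' w <- build_lattice(5)
#' neighbors(w, c(1, 1))
#' @export
build_lattice <- function(side, grid = alpha_grid(4), strict = FALSE) {
  side <- as.integer(side)
  stopifnot(length(side) == 1L, !is.na(side))
  if (side < 2L || (strict && side < 3L)) {
    stop(sprintf("degenerate lattice: side = %d (need side >= %d)",
                 side, if (strict) 3L else 2L), call. = FALSE)
  }
  stopifnot(inherits(grid, "alpha_grid"))
  structure(
    list(
      side = side,
      grid = grid,
      s = matrix(NA_integer_, side, side),
      alpha_idx = matrix(NA_integer_, side, side)
    ),
    class = "lattice_world"
  )
}

#' Von Neumann neighbours of a site
#'
#' Returns the four orthogonal neighbours of `site` under periodic
#' wrap-around, in the fixed order north, south, west, east (row - 1,
#' row + 1, column - 1, column + 1). The fixed order makes per-seed runs
#' bit-reproducible.
#'
#' @param world A [build_lattice()] world.
#' @param site Integer vector `c(row, column)`, 1-based.
#' @return A 4 x 2 integer matrix, one `(row, column)` pair per row, ordered
#'   N, S, W, E.
#' @export
neighbors <- function(world, site) {
  stopifnot(inherits(world, "lattice_world"))
  site <- as.integer(site)
  n <- world$side
  if (length(site) != 2L || any(is.na(site)) ||
      any(site < 1L) || any(site > n)) {
    stop(sprintf("site (%s) out of bounds for side %d",
                 paste(site, collapse = ", "), n), call. = FALSE)
  }
  r <- site[1L]
  cc <- site[2L]
  wrap <- function(i) ((i - 1L) %% n) + 1L
  out <- rbind(
    c(wrap(r - 1L), cc),  # N
    c(wrap(r + 1L), cc),  # S
    c(r, wrap(cc - 1L)),  # W
    c(r, wrap(cc + 1L))   # E
  )
  dimnames(out) <- list(c("N", "S", "W", "E"), c("row", "col"))
  out
}

#' Population size of a world
#' @param world A `lattice_world`.
#' @return Integer `side^2`.
#' @export
n_agents <- function(world) {
  stopifnot(inherits(world, "lattice_world"))
  world$side * world$side
}

#' Per-agent abstention probabilities of a world
#' @param world A populated `lattice_world`.
#' @return Numeric matrix of alpha values (levels looked up from the grid).
#' @export
alpha_values <- function(world) {
  stopifnot(inherits(world, "lattice_world"))
  matrix(world$grid$levels[world$alpha_idx + 1L], world$side, world$side)
}

is_populated <- function(world) {
  !anyNA(world$s) && !anyNA(world$alpha_idx)
}

assert_populated <- function(world) {
  stopifnot(inherits(world, "lattice_world"))
  if (!is_populated(world)) {
    stop("world is not populated; call init_population() first", call. = FALSE)
  }
  invisible(world)
}

#' Construct a world directly from state matrices
#'
#' Mainly for tests and fixtures: wraps explicit strategy and
#' abstention-index matrices into a `lattice_world`.
#'
#' @param s Integer matrix of strategies (0 = C, 1 = D).
#' @param alpha_idx Integer matrix of 0-based indices into `grid$levels`.
#' @param grid An [alpha_grid()].
#' @return A populated `lattice_world`.
#' @export
world_from_matrices <- function(s, alpha_idx, grid = alpha_grid(4)) {
  stopifnot(is.matrix(s), is.matrix(alpha_idx),
            nrow(s) == ncol(s), all(dim(s) == dim(alpha_idx)))
  stopifnot(all(s %in% c(0L, 1L)),
            all(alpha_idx >= 0L & alpha_idx < length(grid$levels)))
  w <- build_lattice(nrow(s), grid)
  w$s <- matrix(as.integer(s), nrow(s), ncol(s))
  w$alpha_idx <- matrix(as.integer(alpha_idx), nrow(s), ncol(s))
  w
}

#' @export
print.lattice_world <- function(x, ...) {
  cat(sprintf("lattice_world: %d x %d torus (N = %d), kappa = %d, %s\n",
              x$side, x$side, n_agents(x), x$grid$kappa,
              if (is_populated(x)) "populated" else "unpopulated"))
  if (is_populated(x)) {
    cat(sprintf("  frac C = %.3f, mean alpha = %.3f\n",
                mean(x$s == 0L), mean(alpha_values(x))))
  }
  invisible(x)
}
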