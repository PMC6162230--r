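# Naive pure-R reference implementations of the synchronous dynamics,
# written against the documented RNG-stream order (sites in column-major
# linear order, each resolving its South then East edge, owner's abstention
# drawn before the neighbour's) but otherwise independent of the compiled
# engine: edges are enumerated and the imitation rule applied literally.

oracle_payoff <- function(sx, sy, p) {
  if (sx == 0L) {
    if (sy == 0L) p$R else p$S
  } else {
    if (sy == 0L) p$T else p$P
  }
}

oracle_accrue_sync <- function(world, params) {
  n <- world$side
  u <- matrix(0, n, n)
  alpha <- alpha_values(world)
  wrap <- function(i) ((i - 1L) %% n) + 1L
  for (lin in 0:(n * n - 1L)) {
    row <- lin %% n + 1L
    col <- lin %/% n + 1L
    south <- c(wrap(row + 1L), col)
    east <- c(row, wrap(col + 1L))
    for (nb in list(south, east)) {
      abst_i <- runif(1) < alpha[row, col]
      abst_j <- runif(1) < alpha[nb[1], nb[2]]
      if (abst_i || abst_j) {
        u[row, col] <- u[row, col] + params$L
        u[nb[1], nb[2]] <- u[nb[1], nb[2]] + params$L
      } else {
        si <- world$s[row, col]
        sj <- world$s[nb[1], nb[2]]
        u[row, col] <- u[row, col] + oracle_payoff(si, sj, params)
        u[nb[1], nb[2]] <- u[nb[1], nb[2]] + oracle_payoff(sj, si, params)
      }
    }
  }
  u
}

oracle_imitate_sync <- function(world, u, tol = 1e-9) {
  n <- world$side
  wrap <- function(i) ((i - 1L) %% n) + 1L
  s_new <- world$s
  a_new <- world$alpha_idx
  for (row in seq_len(n)) {
    for (col in seq_len(n)) {
      nbs <- list(c(wrap(row - 1L), col), c(wrap(row + 1L), col),
                  c(row, wrap(col - 1L)), c(row, wrap(col + 1L)))
      u_nb <- vapply(nbs, function(x) u[x[1], x[2]], numeric(1))
      m <- max(u_nb)
      ties <- sum(abs(u_nb - m) <= tol)
      if (ties == 1L && m > u[row, col] + tol) {
        best <- nbs[[which.max(u_nb)]]
        s_new[row, col] <- world$s[best[1], best[2]]
        a_new[row, col] <- world$alpha_idx[best[1], best[2]]
      }
    }
  }
  world$s <- s_new
  world$alpha_idx <- a_new
  world
}

oracle_sync_step <- function(world, params) {
  oracle_imitate_sync(world, oracle_accrue_sync(world, params))
}

# PD-only reference: no abstention machinery at all. Valid comparator for
# pd-mode worlds (all alpha = 0), where the synchronous trajectory is
# deterministic.
oracle_pd_sync_step <- function(world, params) {
  n <- world$side
  u <- matrix(0, n, n)
  wrap <- function(i) ((i - 1L) %% n) + 1L
  for (row in seq_len(n)) {
    for (col in seq_len(n)) {
      for (nb in list(c(wrap(row + 1L), col), c(row, wrap(col + 1L)))) {
        si <- world$s[row, col]
        sj <- world$s[nb[1], nb[2]]
        u[row, col] <- u[row, col] + oracle_payoff(si, sj, params)
        u[nb[1], nb[2]] <- u[nb[1], nb[2]] + oracle_payoff(sj, si, params)
      }
    }
  }
  oracle_imitate_sync(world, u)
}

random_world <- function(side, grid = alpha_grid(4)) {
  nlev <- length(grid$levels)
  world_from_matrices(
    matrix(sample(0:1, side^2, replace = TRUE), side, side),
    matrix(sample(0:(nlev - 1L), side^2, replace = TRUE), side, side),
    grid
  )
}
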