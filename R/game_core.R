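#' Game parameters for the prisoner's dilemma with probabilistic abstention
#'
#' Bundles the payoff constants and the imitation noise amplitude. The
#' canonical parameterisation fixes the reward for mutual cooperation
#' `R = 1`, the punishment for mutual defection `P = 0` and the sucker's
#' payoff `S = 0`, leaving the temptation to defect `T` and the loner's
#' payoff `L` free. The dilemma is well posed when `1 < T < 2` and
#' `0 < L < 1` (so that `T > R > L > P >= S`).
#'
#' @param T Temptation to defect (payoff to a defector meeting a cooperator).
#' @param L Loner's payoff, received by both parties when either abstains.
#' @param R Reward for mutual cooperation. Default 1.
#' @param P Punishment for mutual defection. Default 0.
#' @param S Sucker's payoff (cooperator meeting a defector). Default 0.
#' @param K Noise amplitude of the Fermi imitation rule; must be positive.
#'   Default 0.1.
#' @param strict If `TRUE`, out-of-range `T` or `L` is an error; if `FALSE`
#'   (default) it only triggers a warning, so limiting cases such as `T = 1`
#'   remain runnable.
#'
#' @return An object of class `game_params`.
#' @examples
#' game_params(T = 1.4, L = 0.4)
#' @seealso [validate_params()], [payoff_pair()]
#' @export
game_params <- function(T = 1.4, L = 0.4, R = 1, P = 0, S = 0, K = 0.1,
                        strict = FALSE) {
  vals <- c(T = T, L = L, R = R, P = P, S = S, K = K)
  if (!all(is.finite(vals))) {
    stop("all game parameters must be finite numbers", call. = FALSE)
  }
  if (K <= 0) {
    stop("noise amplitude K must be positive", call. = FALSE)
  }
  params <- structure(
    list(T = T, L = L, R = R, P = P, S = S, K = K, strict = strict),
    class = "game_params"
  )
  validate_params(params)
}

#' Validate the dilemma bounds of a parameter set
#'
#' Checks `1 < T < 2` and `0 < L < 1`. In strict mode a violation is an
#' error naming the offending bound; otherwise it is a warning and the
#' parameters are returned unchanged, since the bounds delimit the dilemma
#' regime rather than the domain on which the payoffs are defined.
#'
#' @param params A [game_params()] object.
#' @param strict Override the strictness recorded in `params`.
#' @return `params`, invisibly unchanged, if acceptable.
#' @export
validate_params <- function(params, strict = params$strict) {
  stopifnot(inherits(params, "game_params"))
  bad <- character(0)
  if (!(params$T > 1 && params$T < 2)) {
    bad <- c(bad, sprintf("T = %g violates 1 < T < 2", params$T))
  }
  if (!(params$L > 0 && params$L < 1)) {
    bad <- c(bad, sprintf("L = %g violates 0 < L < 1", params$L))
  }
  if (length(bad)) {
    msg <- paste0("invalid dilemma: ", paste(bad, collapse = "; "))
    if (isTRUE(strict)) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  params
}

#' Admissible abstention-probability levels
#'
#' The abstention probability \eqn{\alpha} is discretized to `2 * kappa`
#' equal intervals, where `kappa` is the agent degree, giving
#' `2 * kappa + 1` levels `i / (2 * kappa)` for `i = 0, ..., 2 * kappa`.
#' On the von Neumann lattice (`kappa = 4`) these are
#' 0, 0.125, 0.25, ..., 0.875, 1.
#'
#' @param kappa Agent degree (number of neighbours); a positive integer.
#' @return An object of class `alpha_grid` with fields `kappa` and `levels`.
#' @examples
#' alpha_grid(4)$levels
#' @export
alpha_grid <- function(kappa = 4) {
  kappa <- as.integer(kappa)
  stopifnot(length(kappa) == 1L, !is.na(kappa), kappa >= 1L)
  structure(
    list(kappa = kappa, levels = seq(0, 1, length.out = 2L * kappa + 1L)),
    class = "alpha_grid"
  )
}

#' Payoffs of one pairwise interaction
#'
#' If either party abstains, both receive the loner's payoff `L`. Otherwise
#' the payoffs follow the classic prisoner's dilemma matrix: mutual
#' cooperation pays `(R, R)`, mutual defection `(P, P)`, and a defector
#' meeting a cooperator receives `T` while the cooperator receives `S`.
#'
#' @param sx,sy Strategies of the focal agent and the partner; 0 = cooperate,
#'   1 = defect.
#' @param abstain_x,abstain_y Logical; whether each party abstains from this
#'   interaction.
#' @param params A [game_params()] object.
#' @return Named numeric vector `c(x = payoff to x, y = payoff to y)`.
#' @examples
#' p <- game_params(T = 1.4, L = 0.4)
#' payoff_pair(1, 0, FALSE, FALSE, p) # defector exploits cooperator: (1.4, 0)
#' payoff_pair(1, 1, TRUE, FALSE, p)  # abstained: both get L
#' @export
payoff_pair <- function(sx, sy, abstain_x, abstain_y, params) {
  stopifnot(sx %in% c(0, 1), sy %in% c(0, 1),
            is.logical(abstain_x), is.logical(abstain_y))
  if (abstain_x || abstain_y) {
    return(c(x = params$L, y = params$L))
  }
  if (sx == 0 && sy == 0) {
    c(x = params$R, y = params$R)
  } else if (sx == 0 && sy == 1) {
    c(x = params$S, y = params$T)
  } else if (sx == 1 && sy == 0) {
    c(x = params$T, y = params$S)
  } else {
    c(x = params$P, y = params$P)
  }
}

#' Draw abstention decisions
#'
#' Bernoulli draws from R's current random-number stream: each draw is
#' `TRUE` (abstain) with probability `alpha`, independently.
#'
#' @param alpha Abstention probability in `[0, 1]`.
#' @param n Number of independent draws.
#' @return Logical vector of length `n`.
#' @export
draw_abstention <- function(alpha, n = 1L) {
  stopifnot(length(alpha) == 1L, alpha >= 0, alpha <= 1)
  runif(n) < alpha
}

#' Effective cooperation rate
#'
#' The probability that an agent both is a cooperator and actually plays:
#' \eqn{\epsilon = (1 - s)(1 - \alpha)}. Any defector has \eqn{\epsilon = 0};
#' a pure cooperator (\eqn{\alpha = 0}) has \eqn{\epsilon = 1}; a cooperator
#' who always abstains (\eqn{\alpha = 1}) has \eqn{\epsilon = 0}.
#'
#' @param s Strategy, 0 = cooperate or 1 = defect (vectorized).
#' @param alpha Abstention probability in `[0, 1]` (vectorized).
#' @return Numeric vector of rates in `[0, 1]`.
#' @examples
#' effective_cooperation(0, 0.25) # a sporadic cooperator: 0.75
#' effective_cooperation(1, 0)    # any defector: 0
#' @export
effective_cooperation <- function(s, alpha) {
  stopifnot(all(s %in% c(0, 1)), all(alpha >= 0 & alpha <= 1))
  (1 - s) * (1 - alpha)
}

#' @export
print.game_params <- function(x, ...) {
  cat(sprintf(
    "game_params: T = %g, R = %g, L = %g, P = %g, S = %g, K = %g%s\n",
    x$T, x$R, x$L, x$P, x$S, x$K, if (x$strict) " (strict)" else ""
  ))
  invisible(x)
}

#' @export
print.alpha_grid <- function(x, ...) {
  cat(sprintf("alpha_grid: kappa = %d, %d levels: %s\n",
              x$kappa, length(x$levels),
              paste(format(x$levels), collapse = " ")))
  invisible(x)
}
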