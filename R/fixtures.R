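#' Deterministic fixture worlds
#'
#' A small catalogue of hand-constructed lattices used throughout the test
#' suite and documentation:
#' \describe{
#'   \item{`"single_c_3x3"`}{3 x 3 torus, all defectors with `alpha = 0`
#'     except a lone cooperator at the centre. With `T = 1.4` its
#'     synchronous utilities can be enumerated by hand (centre 0, its four
#'     neighbours 1.4, the rest 0).}
#'   \item{`"all_loners_5x5"`}{5 x 5 torus, checkerboard strategies, every
#'     agent at `alpha = 1`: every interaction is abstained, so all
#'     utilities equal `4 L` and the state is frozen.}
#'   \item{`"checkerboard_4x4"`}{4 x 4 torus, alternating cooperators and
#'     defectors, all `alpha = 0`.}
#'   \item{`"two_level_split_6x6"`}{6 x 6 torus, checkerboard strategies;
#'     the left three columns never abstain (`alpha = 0`), the right three
#'     always abstain (`alpha = 1`).}
#' }
#'
#' @param name Fixture id (see above).
#' @return A populated `lattice_world`.
#' @examples
#' make_fixture("single_c_3x3")
#' @export
make_fixture <- function(name) {
  grid <- alpha_grid(4)
  top <- length(grid$levels) - 1L
  checker <- function(side) {
    matrix(as.integer((outer(seq_len(side), seq_len(side), `+`)) %% 2L),
           side, side)
  }
  switch(name,
    single_c_3x3 = {
      s <- matrix(1L, 3, 3)
      s[2, 2] <- 0L
      world_from_matrices(s, matrix(0L, 3, 3), grid)
    },
    all_loners_5x5 = {
      world_from_matrices(checker(5L), matrix(top, 5, 5), grid)
    },
    checkerboard_4x4 = {
      world_from_matrices(checker(4L), matrix(0L, 4, 4), grid)
    },
    two_level_split_6x6 = {
      a <- matrix(0L, 6, 6)
      a[, 4:6] <- top
      world_from_matrices(checker(6L), a, grid)
    },
    stop(sprintf("unknown fixture '%s'; catalogue: %s", name,
                 paste(fixture_names(), collapse = ", ")), call. = FALSE)
  )
}

#' @rdname make_fixture
#' @export
fixture_names <- function() {
  c("single_c_3x3", "all_loners_5x5", "checkerboard_4x4",
    "two_level_split_6x6")
}
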