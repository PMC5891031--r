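#' @useDynLib wgdresolve, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## State order used everywhere in the package:
##   U  = undifferentiated duplicate
##   F  = fixed duplicate (absorbing)
##   S1 = single copy retained from parental subgenome 1 (absorbing)
##   S2 = single copy retained from parental subgenome 2 (absorbing)
WGD_STATES <- c("U", "F", "S1", "S2")

#' Instantaneous rate matrix of the duplicate-loss model
#'
#' Builds the 4-state generator of the post-WGD duplicate resolution model.
#' The states are `U` (undifferentiated duplicate), `F` (fixed duplicate) and
#' the two single-copy states `S1`/`S2`, one per parental subgenome. `F`,
#' `S1` and `S2` are absorbing. The base loss rate into `S1` is fixed to 1 so
#' that branch lengths are measured in units of (loss rate alpha) x time;
#' losses into `S2` occur at relative rate `epsilon` (the fractionation bias:
#' `epsilon < 1` means subgenome 2 loses its surviving single copies less
#' often, i.e. subgenome 1 copies are retained preferentially -- see Details)
#' and duplicate fixation at relative rate `gamma`.
#'
#' @details
#' With this parameterisation the ratio of expected losses ending in `S2` to
#' those ending in `S1` equals `epsilon` on every branch, so the maximum
#' likelihood estimate of `epsilon` can be read directly as the retention
#' ratio of subgenome-2-derived single copies relative to subgenome-1-derived
#' ones. Subgenome 2 is, by convention, the more fractionated subgenome; its
#' identity is inferred from the data.
#'
#' @param gamma relative fixation rate, `0 <= gamma < Inf`.
#' @param epsilon fractionation bias, `0 <= epsilon <= 1`.
#' @return A 4x4 numeric matrix with dimnames `U`, `F`, `S1`, `S2`; rows sum
#'   to zero and the three absorbing rows are identically zero.
#' @examples
#' loss_rate_matrix(gamma = 0, epsilon = 1)
#' @seealso [loss_transition_probs()]
#' @export
loss_rate_matrix <- function(gamma, epsilon) {
  check_loss_params(gamma, epsilon)
  Q <- matrix(0, 4L, 4L, dimnames = list(WGD_STATES, WGD_STATES))
  Q["U", "F"]  <- gamma
  Q["U", "S1"] <- 1
  Q["U", "S2"] <- epsilon
  Q["U", "U"]  <- -(1 + epsilon + gamma)
  Q
}

#' Transition probabilities of the duplicate-loss model
#'
#' Closed-form transition probability matrix `P(b) = exp(Q b)` for the
#' generator of [loss_rate_matrix()] over a branch of length `b` (in
#' alpha x time units). Because all states but `U` are absorbing the matrix
#' exponential has an elementary form: with total outflow
#' `r = 1 + epsilon + gamma`,
#' `P(U -> U) = exp(-r b)` and `P(U -> S1) = (1 - exp(-r b)) / r`, with the
#' `S2` and `F` entries scaled by `epsilon` and `gamma` respectively.
#'
#' @inheritParams loss_rate_matrix
#' @param b branch length, `b >= 0`.
#' @return A 4x4 row-stochastic matrix in the `U`, `F`, `S1`, `S2` order.
#' @examples
#' loss_transition_probs(gamma = 0.17, epsilon = 0.65, b = 0.5)
#' @export
loss_transition_probs <- function(gamma, epsilon, b) {
  check_loss_params(gamma, epsilon)
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b < 0)
    stop("branch length `b` must be a single non-negative number", call. = FALSE)
  r <- 1 + epsilon + gamma
  puu <- exp(-r * b)
  w <- (1 - puu) / r
  P <- diag(4)
  dimnames(P) <- list(WGD_STATES, WGD_STATES)
  P["U", ] <- c(puu, gamma * w, w, epsilon * w)
  P
}

check_loss_params <- function(gamma, epsilon) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) || gamma < 0)
    stop("`gamma` must be a single number >= 0", call. = FALSE)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) ||
      epsilon < 0 || epsilon > 1)
    stop("`epsilon` must be a single number in [0, 1]", call. = FALSE)
  invisible(TRUE)
}
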