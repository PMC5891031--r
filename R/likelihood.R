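#' Tip state likelihoods for one genome's observation
#'
#' Encodes how a pillar observation constrains the four model states at a
#' tip, given the genome's subgenome assignment. A duplicated observation is
#' compatible with both duplicated states (`U`, `F`). A single-copy gene in
#' slot `p1` is in state `S1` when the genome's slot-1 track maps to
#' subgenome 1 (`assignment = 1`) and in `S2` otherwise; a single copy in
#' slot `p2` is the mirror image.
#'
#' @param obs observation: `"duplicated"`, `"single_in_p1"`,
#'   `"single_in_p2"` or the integer codes 1:3.
#' @param assignment 1 or 2: the parental subgenome of the genome's slot-1
#'   track.
#' @return Named numeric 4-vector over states `U`, `F`, `S1`, `S2`.
#' @examples
#' tip_likelihood("single_in_p1", 1)
#' @export
tip_likelihood <- function(obs, assignment) {
  if (is.character(obs)) obs <- match(obs, OBS_LEVELS)
  if (length(obs) != 1L || is.na(obs) || !obs %in% 1:3)
    stop("`obs` must be a single observation (duplicated / single_in_p1 / single_in_p2)",
         call. = FALSE)
  if (length(assignment) != 1L || !assignment %in% 1:2)
    stop("`assignment` must be 1 or 2", call. = FALSE)
  out <- c(U = 0, F = 0, S1 = 0, S2 = 0)
  if (obs == OBS_DUPLICATED) out[c("U", "F")] <- 1
  else if (obs == OBS_SINGLE_P1) out[if (assignment == 1L) "S1" else "S2"] <- 1
  else out[if (assignment == 1L) "S2" else "S1"] <- 1
  out
}

#' Log-likelihood of one pillar under a fixed assignment vector
#'
#' Computes, by Felsenstein pruning with the root pinned to state `U`, the
#' probability of one pillar's observations given a fixed subgenome
#' assignment vector. This is the emission probability of the
#' assignment-vector HMM at that pillar, evaluated in plain R; the batch
#' engine behind [sequence_loglik()] computes the same quantity for all
#' `2^n` vectors at once in compiled code.
#'
#' @param pillars a [pillar_set()].
#' @param index pillar index.
#' @param assignment integer vector over `{1, 2}`, one entry per genome (in
#'   the pillar set's genome order).
#' @param model a [loss_model()].
#' @return Log-likelihood (may be `-Inf` for impossible assignments).
#' @export
pillar_loglik <- function(pillars, index, assignment, model) {
  stopifnot(inherits(pillars, "pillar_set"))
  if (length(assignment) != n_genomes(pillars) || !all(assignment %in% 1:2))
    stop("`assignment` must be a {1,2}-vector with one entry per genome", call. = FALSE)
  inp <- engine_inputs(pillars, model)
  obs <- pillars$obs[index, ]
  P <- edge_transition_array(model)
  tree <- inp$tree
  inside <- matrix(1, inp$n_nodes, 4L)
  for (t in seq_along(tree$tip.label)) {
    g <- inp$tip_genome[t]
    inside[t, ] <- tip_likelihood(obs[g], assignment[g])
  }
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    inside[par, ] <- inside[par, ] * as.vector(P[, , e] %*% inside[ch, ])
  }
  log(inside[inp$root, 1L])
}

#' Transition kernel of the assignment HMM at one junction
#'
#' The hidden chain over assignment vectors moves between adjacent pillars
#' by independent per-genome flips: genome `g` keeps its assignment with
#' probability `1 - theta_g` and flips with `theta_g`, where `theta_g` is
#' the model's global `theta` unless genome `g` carries a double synteny
#' break at this junction, in which case `theta_g = 0.5` and the genome's
#' assignment decorrelates completely. The full kernel is the Kronecker
#' product of the per-genome 2x2 kernels.
#'
#' @inheritParams pillar_loglik
#' @param junction junction index (`1` = between pillars 1 and 2).
#' @return A `2^n` x `2^n` row-stochastic matrix in assignment-vector index
#'   order (see [assignment_vectors()]).
#' @export
junction_transition <- function(pillars, model, junction) {
  inp <- engine_inputs(pillars, model)
  if (junction < 1L || junction > inp$m - 1L)
    stop("`junction` must be in 1..(n_pillars - 1)", call. = FALSE)
  K <- matrix(1, 1L, 1L)
  for (g in seq_len(inp$n)) {
    th <- inp$flip[junction, g]
    Kg <- matrix(c(1 - th, th, th, 1 - th), 2L, 2L)
    K <- Kg %x% K  # genome 1 varies fastest: low bit of the vector index
  }
  K
}

#' Total log-likelihood of an ordered pillar set
#'
#' Evaluates the joint likelihood of all pillars under the duplicate-loss
#' model: per-pillar emission probabilities for every subgenome assignment
#' vector are obtained by pruning along the tree, and the hidden chain of
#' assignment vectors along the ancestral gene order is integrated out by a
#' scaled forward pass (uniform initial distribution over the `2^n`
#' vectors).
#'
#' @inheritParams pillar_loglik
#' @return The total log-likelihood (scalar).
#' @export
sequence_loglik <- function(pillars, model) {
  inp <- engine_inputs(pillars, model)
  em <- pillar_emissions(pillars, model, inp)
  if (em$dead) return(-Inf)
  h <- cpp_hmm(em$emis, inp$flip, FALSE)
  h$loglik + sum(em$log_scale)
}

#' Posterior decoding of subgenome assignments
#'
#' Runs the forward-backward algorithm over the hidden chain of assignment
#' vectors and returns, for every pillar, the posterior distribution over
#' all `2^n` vectors together with the per-genome marginal probability that
#' the genome's slot-1 track derives from parental subgenome 1.
#'
#' @inheritParams pillar_loglik
#' @return An object of class `wgd_posterior`: a list with elements
#'   `prob` (`m` x `2^n` matrix, rows sum to 1), `marginal1` (`m` x `n`
#'   matrix of per-genome subgenome-1 marginals), `loglik`, `vectors`
#'   (the assignment vectors, as from [assignment_vectors()]) and `genomes`.
#' @export
posterior_assignments <- function(pillars, model) {
  inp <- engine_inputs(pillars, model)
  em <- pillar_emissions(pillars, model, inp)
  if (em$dead) stop("data have zero likelihood under this model", call. = FALSE)
  h <- cpp_hmm(em$emis, inp$flip, TRUE)
  vecs <- assignment_vectors(pillars$genomes)
  marg1 <- h$posterior %*% (vecs == 1L)
  colnames(marg1) <- pillars$genomes
  structure(list(prob = h$posterior, marginal1 = marg1,
                 loglik = h$loglik + sum(em$log_scale),
                 vectors = vecs, genomes = pillars$genomes),
            class = "wgd_posterior")
}

#' @export
print.wgd_posterior <- function(x, ...) {
  cat(sprintf("wgd_posterior: %d pillars, %d assignment vectors, logLik = %.4f\n",
              nrow(x$prob), ncol(x$prob), x$loglik))
  cat("  mean per-genome subgenome-1 marginal:\n")
  print(round(colMeans(x$marginal1), 4))
  invisible(x)
}

#' Expected per-branch loss and fixation counts
#'
#' For every branch of the tree, the expected number of pillars whose
#' duplicate pair was resolved on that branch: transitions `U -> S1`
#' (single copy retained from subgenome 1), `U -> S2` and `U -> F`
#' (fixation). Because the three target states are absorbing, a resolution
#' happened on branch `e` precisely when the state is `U` at its parent node
#' and the target state at its child node; the expectation weights these
#' joint events by the HMM posterior over assignment vectors and by the
#' within-pillar state posterior from an inside-outside pass. The per-branch
#' ratio `E[U -> S2] / E[U -> S1]` estimates the retention ratio of
#' subgenome 2 relative to subgenome 1 on that branch.
#'
#' @inheritParams pillar_loglik
#' @param posterior optionally, a precomputed [posterior_assignments()]
#'   result for the same pillars and model.
#' @return A data frame with one row per edge (postorder order): `edge`,
#'   `parent`, `child`, `label` (tip name or internal node id),
#'   `n_to_S1`, `n_to_S2`, `n_to_F` and `ratio_S2_S1` (`NA` where
#'   `n_to_S1` is zero).
#' @export
expected_loss_counts <- function(pillars, model, posterior = NULL) {
  inp <- engine_inputs(pillars, model)
  if (is.null(posterior)) posterior <- posterior_assignments(pillars, model)
  P <- edge_transition_array(model)
  cond <- cpp_branch_loss_cond(inp$patterns, inp$tree$edge, as.numeric(P),
                               as.integer(inp$tip_genome), inp$n_nodes, inp$root)
  npat <- nrow(inp$patterns); S <- inp$S; E <- nrow(inp$tree$edge)
  ## aggregate posterior mass per (pattern, vector)
  W <- rowsum(posterior$prob, group = inp$pattern_idx)
  Wfull <- matrix(0, npat, S)
  Wfull[as.integer(rownames(W)), ] <- W
  counts <- crossprod(matrix(cond, npat * S, E * 3L), as.vector(Wfull))
  counts <- matrix(counts, E, 3L)
  child <- inp$tree$edge[, 2L]
  lab <- ifelse(child <= length(inp$tree$tip.label),
                inp$tree$tip.label[child], paste0("node", child))
  data.frame(edge = seq_len(E), parent = inp$tree$edge[, 1L], child = child,
             label = lab,
             n_to_S1 = counts[, 1L], n_to_S2 = counts[, 2L], n_to_F = counts[, 3L],
             ratio_S2_S1 = ifelse(counts[, 1L] > 0, counts[, 2L] / counts[, 1L], NA_real_))
}

#' Segment the ancestral order into consistent subgenome blocks
#'
#' Scans the pillar order and reports maximal runs in which at least
#' `min_genomes` genomes keep the same high-confidence subgenome assignment
#' between every pair of adjacent pillars. A genome "agrees" across a
#' junction when its subgenome-1 marginal is on the same side of 0.5 at both
#' pillars with confidence at least `confidence` at both. Junctions where
#' every genome carries a double synteny break always terminate a block
#' (assignments are independent across such junctions).
#'
#' @param posterior a [posterior_assignments()] result.
#' @param pillars the [pillar_set()] the posterior was computed from (source
#'   of the double-break flags).
#' @param confidence assignment confidence required per genome (default
#'   0.85).
#' @param min_genomes how many genomes must agree across every junction
#'   inside a block (default: all).
#' @return Data frame with columns `block`, `start`, `end`, `n_pillars`.
#' @export
block_segmentation <- function(posterior, pillars, confidence = 0.85,
                               min_genomes = n_genomes(pillars)) {
  stopifnot(inherits(posterior, "wgd_posterior"), inherits(pillars, "pillar_set"))
  n <- n_genomes(pillars); m <- n_pillars(pillars)
  if (min_genomes > n) stop("`min_genomes` exceeds the number of genomes", call. = FALSE)
  marg <- posterior$marginal1
  assign <- ifelse(marg >= 0.5, 1L, 2L)
  conf <- pmax(marg, 1 - marg)
  if (m == 1L)
    return(data.frame(block = 1L, start = 1L, end = 1L, n_pillars = 1L))
  agree <- (assign[-m, , drop = FALSE] == assign[-1L, , drop = FALSE]) &
    (conf[-m, , drop = FALSE] >= confidence) &
    (conf[-1L, , drop = FALSE] >= confidence)
  link <- rowSums(agree) >= min_genomes
  link[rowSums(pillars$double_break) == n] <- FALSE
  starts <- c(1L, which(!link) + 1L)
  ends <- c(which(!link), m)
  data.frame(block = seq_along(starts), start = starts, end = ends,
             n_pillars = ends - starts + 1L)
}
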