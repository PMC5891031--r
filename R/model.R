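#' Duplicate-loss model along a phylogeny
#'
#' Bundles a rooted tree of the polyploid genomes (branch lengths in
#' alpha x time units, where alpha is the base duplicate-loss rate), the
#' global loss parameters `gamma` (relative fixation rate) and `epsilon`
#' (fractionation bias), and the junction switching probability `theta` of
#' the hidden Markov chain over subgenome assignment vectors. Optionally
#' `epsilon` may take a different value `epsilon_early` on a designated
#' "early" class of branches (by default the branches incident to the root,
#' i.e. the shared post-WGD interval), which is the temporal-bias model used
#' to ask whether biased fractionation was concentrated immediately after
#' the polyploidy.
#'
#' @param tree a rooted `phylo` tree whose tip labels are the genome names
#'   and whose root is the WGD event (every locus starts there in state `U`).
#' @param gamma relative fixation rate (`>= 0`).
#' @param epsilon fractionation bias in `[0, 1]` (applies to all branches,
#'   or to the non-early branches when `epsilon_early` is given).
#' @param theta junction switching probability in `[0, 0.5]`: the per-genome
#'   probability that the subgenome assignment flips between adjacent
#'   pillars (replaced by 0.5 at flagged double synteny breaks).
#' @param epsilon_early optional fractionation bias for the early branch
#'   class.
#' @param early_edges integer indices of the early edges, referring to rows
#'   of the postorder edge matrix of the stored tree (see [root_edges()]);
#'   defaults to the edges incident to the root.
#' @return An object of class `wgd_loss_model`.
#' @examples
#' tr <- ape::read.tree(text = "((gA:0.3,gB:0.3):0.2,gC:0.5);")
#' loss_model(tr, gamma = 0.17, epsilon = 0.65, theta = 0.005)
#' @export
loss_model <- function(tree, gamma = 0, epsilon = 1, theta = 0.01,
                       epsilon_early = NULL, early_edges = NULL) {
  if (!inherits(tree, "phylo")) stop("`tree` must be an ape phylo object", call. = FALSE)
  if (is.null(tree$edge.length)) stop("`tree` must carry branch lengths", call. = FALSE)
  if (!ape::is.rooted(tree)) stop("`tree` must be rooted at the WGD event", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0", call. = FALSE)
  check_loss_params(gamma, epsilon)
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta < 0 || theta > 0.5)
    stop("`theta` must be in [0, 0.5]", call. = FALSE)
  tree <- stats::reorder(tree, "postorder")
  E <- nrow(tree$edge)
  if (!is.null(epsilon_early)) {
    check_loss_params(gamma, epsilon_early)
    if (is.null(early_edges)) early_edges <- root_edges(tree)
    early_edges <- as.integer(early_edges)
    if (any(early_edges < 1L | early_edges > E))
      stop("`early_edges` out of range", call. = FALSE)
  } else {
    early_edges <- integer(0)
  }
  structure(list(tree = tree, gamma = gamma, epsilon = epsilon, theta = theta,
                 epsilon_early = epsilon_early, early_edges = early_edges),
            class = "wgd_loss_model")
}

#' @export
print.wgd_loss_model <- function(x, ...) {
  cat(sprintf("wgd_loss_model: %d genomes, gamma=%.4g, epsilon=%.4g%s, theta=%.4g\n",
              length(x$tree$tip.label), x$gamma, x$epsilon,
              if (!is.null(x$epsilon_early))
                sprintf(" (early branches: epsilon=%.4g)", x$epsilon_early) else "",
              x$theta))
  invisible(x)
}

#' Edges incident to the root of a tree
#'
#' Returns the indices (rows of the postorder edge matrix) of the branches
#' whose parent node is the root. These form the default "early" branch
#' class of the temporal-bias model: the shared interval immediately after
#' the WGD.
#'
#' @param tree a rooted `phylo` object.
#' @return Integer vector of edge indices into the postorder edge matrix.
#' @export
root_edges <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  root <- ape::Ntip(tree) + 1L
  which(tree$edge[, 1L] == root)
}

## Per-edge epsilon values of a model (early class substituted).
edge_epsilons <- function(model) {
  eps <- rep(model$epsilon, nrow(model$tree$edge))
  if (length(model$early_edges)) eps[model$early_edges] <- model$epsilon_early
  eps
}

## 4 x 4 x E array of per-edge transition matrices.
edge_transition_array <- function(model) {
  tree <- model$tree
  E <- nrow(tree$edge)
  eps <- edge_epsilons(model)
  P <- array(0, dim = c(4L, 4L, E))
  for (e in seq_len(E))
    P[, , e] <- loss_transition_probs(model$gamma, eps[e], tree$edge.length[e])
  P
}

## Shared preparation for the C++ engine: genome/tip matching, unique
## observation patterns and the per-junction flip-probability matrix.
engine_inputs <- function(pillars, model) {
  stopifnot(inherits(pillars, "pillar_set"), inherits(model, "wgd_loss_model"))
  n <- n_genomes(pillars)
  if (n > 12L)
    stop("assignment state space 2^n capped at n = 12 genomes; ",
         "split the analysis or reduce the genome set", call. = FALSE)
  tree <- model$tree
  if (length(tree$tip.label) != n || !setequal(tree$tip.label, pillars$genomes))
    stop("tree tip labels must match the pillar set's genome names", call. = FALSE)
  tip_genome <- match(tree$tip.label, pillars$genomes)
  pat_key <- apply(pillars$obs, 1L, paste, collapse = ",")
  upat <- !duplicated(pat_key)
  patterns <- pillars$obs[upat, , drop = FALSE]
  pattern_idx <- match(pat_key, pat_key[upat])
  m <- n_pillars(pillars)
  flip <- matrix(model$theta, max(m - 1L, 0L), n)
  flip[pillars$double_break] <- 0.5
  list(n = n, m = m, S = 2L^n, tree = tree, tip_genome = tip_genome,
       patterns = patterns, pattern_idx = pattern_idx, flip = flip,
       n_nodes = max(tree$edge), root = ape::Ntip(tree) + 1L)
}

## Emission likelihoods for every pillar (rows) and assignment vector
## (columns), linear scale, together with per-row log scale factors.
pillar_emissions <- function(pillars, model, inp = engine_inputs(pillars, model)) {
  P <- edge_transition_array(model)
  em <- cpp_pillar_emissions(inp$patterns, inp$tree$edge, as.numeric(P),
                             as.integer(inp$tip_genome), inp$n_nodes, inp$root)
  em <- em[inp$pattern_idx, , drop = FALSE]
  sc <- apply(em, 1L, max)
  if (any(sc <= 0))
    return(list(emis = em, log_scale = rep(-Inf, nrow(em)), dead = TRUE))
  list(emis = em / sc, log_scale = log(sc), dead = FALSE)
}

#' Assignment-vector labels
#'
#' Enumerates the `2^n` subgenome assignment vectors in the index order used
#' by the package: vector `j` (0-based) maps genome `g`'s slot-1 track to
#' subgenome 2 iff bit `g - 1` of `j` is set.
#'
#' @param genomes character vector of genome names.
#' @return Integer matrix (`2^n` x `n`) with entries in `{1, 2}`.
#' @export
assignment_vectors <- function(genomes) {
  n <- length(genomes)
  S <- 2L^n
  v <- matrix(1L, S, n, dimnames = list(NULL, genomes))
  for (g in seq_len(n))
    v[, g] <- 1L + bitwAnd(seq_len(S) - 1L, bitwShiftL(1L, g - 1L)) %/%
      bitwShiftL(1L, g - 1L)
  v
}
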