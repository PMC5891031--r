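#' Example post-WGD phylogeny
#'
#' A ladder-shaped rooted tree for `n` polyploid genomes with branch lengths
#' (in alpha x time units) chosen to resemble a plant WGD like At-alpha: a
#' long shared root branch on which roughly half of all duplicate pairs are
#' resolved, followed by successive speciations. Used as the default tree of
#' the simulator.
#'
#' @param n_genomes number of genomes (>= 2).
#' @return A rooted `phylo` object with tips `g1 ... gn`.
#' @export
example_wgd_tree <- function(n_genomes = 6L) {
  n <- as.integer(n_genomes)
  if (n < 2L) stop("need at least two genomes", call. = FALSE)
  ## ladder: root -> (deep clade, last tip); root branch ~0.55 like At-alpha
  clade <- "g1:0.20"
  depth <- 0.20
  if (n > 2L) for (i in 2:(n - 1L)) {
    depth <- depth + 0.12
    clade <- sprintf("(%s,g%d:%.2f):0.12", clade, i, depth)
  }
  txt <- sprintf("(%s,g%d:%.2f);",
                 if (n == 2L) clade else clade, n, depth + 0.55)
  tr <- ape::read.tree(text = if (n == 2L)
    sprintf("(g1:0.20,g2:0.75);") else txt)
  ## raise the shared root-ward branch to 0.55
  tr <- stats::reorder(tr, "postorder")
  re <- root_edges(tr)
  internal <- re[tr$edge[re, 2L] > ape::Ntip(tr)]
  if (length(internal)) tr$edge.length[internal] <- 0.55
  tr
}

#' Simulator configuration
#'
#' Collects the generative parameters of the synthetic post-WGD world: the
#' tree (with branch lengths in alpha x time units), the loss-model
#' parameters, the junction behaviour of the hidden assignment chain, the
#' number of pillars and a mandatory seed. Defaults reflect a typical plant
#' WGD: `gamma = 0.17`, `epsilon = 0.65`, `theta = 0.005` and a per-genome
#' double-break rate of 0.026 per junction.
#'
#' @param tree rooted `phylo` with branch lengths; default
#'   [example_wgd_tree()] on 6 genomes.
#' @param m number of pillars.
#' @param gamma,epsilon,theta loss-model parameters (see [loss_model()]).
#' @param double_break_rate per-genome per-junction probability of a double
#'   synteny break (at which the assignment flips with probability 0.5).
#' @param epsilon_early,early_edges optional temporal bias (see
#'   [loss_model()]).
#' @param seed mandatory integer seed.
#' @return A list of class `wgd_sim_config`.
#' @export
wgd_sim_config <- function(tree = example_wgd_tree(6L), m = 5000L,
                           gamma = 0.17, epsilon = 0.65, theta = 0.005,
                           double_break_rate = 0.026,
                           epsilon_early = NULL, early_edges = NULL, seed) {
  if (missing(seed)) stop("`seed` is mandatory for reproducible simulation", call. = FALSE)
  model <- loss_model(tree, gamma = gamma, epsilon = epsilon, theta = theta,
                      epsilon_early = epsilon_early, early_edges = early_edges)
  stopifnot(m >= 1L, double_break_rate >= 0, double_break_rate <= 1)
  structure(list(model = model, m = as.integer(m),
                 double_break_rate = double_break_rate,
                 seed = as.integer(seed)),
            class = "wgd_sim_config")
}

#' Simulate duplicate-resolution states along the tree
#'
#' Evolves every pillar independently down the tree from the root state `U`
#' using the model's transition probabilities, recording the state at every
#' node and the branch on which each pillar was resolved (left `U`). The
#' realized per-branch counts of `U -> S1`, `U -> S2` and `U -> F` events
#' are retained so that posterior expectations can be validated against the
#' truth.
#'
#' @param config a [wgd_sim_config()].
#' @return List with `tip_states` (`m` x `n`, codes 1=U, 2=F, 3=S1, 4=S2,
#'   columns in tip-label order), `node_states` (`m` x `n_nodes`),
#'   `realized_counts` (data frame per edge: `n_to_S1`, `n_to_S2`,
#'   `n_to_F`) and the postorder `tree`.
#' @export
simulate_states <- function(config) {
  stopifnot(inherits(config, "wgd_sim_config"))
  model <- config$model
  tree <- model$tree
  m <- config$m
  set.seed(config$seed)
  eps <- edge_epsilons(model)
  n_nodes <- max(tree$edge)
  root <- ape::Ntip(tree) + 1L
  states <- matrix(NA_integer_, m, n_nodes)
  states[, root] <- 1L
  E <- nrow(tree$edge)
  counts <- matrix(0, E, 3L)
  for (e in rev(seq_len(E))) {  # reverse postorder = parents before children
    par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    P <- loss_transition_probs(model$gamma, eps[e], tree$edge.length[e])
    s <- states[, par]
    out <- s
    inU <- which(s == 1L)
    if (length(inU))
      out[inU] <- sample.int(4L, length(inU), replace = TRUE, prob = P["U", ])
    states[, ch] <- out
    counts[e, ] <- c(sum(s == 1L & out == 3L), sum(s == 1L & out == 4L),
                     sum(s == 1L & out == 2L))
  }
  tips <- states[, seq_len(ape::Ntip(tree)), drop = FALSE]
  colnames(tips) <- tree$tip.label
  list(tip_states = tips, node_states = states,
       realized_counts = data.frame(edge = seq_len(E),
                                    parent = tree$edge[, 1L],
                                    child = tree$edge[, 2L],
                                    n_to_S1 = counts[, 1L],
                                    n_to_S2 = counts[, 2L],
                                    n_to_F = counts[, 3L]),
       tree = tree)
}

#' Simulate a pillar set with known truth
#'
#' Builds a complete synthetic pillar dataset: tip states from
#' [simulate_states()], a hidden per-genome subgenome assignment chain that
#' flips with probability `theta` at each junction (0.5 at planted double
#' synteny breaks), and the resulting slot observations and gene
#' identifiers. The generating truth (assignments, states, realized
#' per-branch loss counts, config) is attached as `$truth`.
#'
#' @param config a [wgd_sim_config()].
#' @param states optionally the result of [simulate_states()] for this
#'   config (it is recomputed, seeded, if omitted). Note that the two-stage
#'   call draws the junction randomness after the state randomness, so
#'   `simulate_pillars(cfg)` is reproducible bit-exactly from `cfg` alone.
#' @return A [pillar_set()] (genome columns in the config's tip-label
#'   order) whose `truth` holds `assignment` (`m` x `n` of 1/2),
#'   `tip_states`, `realized_counts` and `config`.
#' @export
simulate_pillars <- function(config, states = NULL) {
  stopifnot(inherits(config, "wgd_sim_config"))
  if (is.null(states)) states <- simulate_states(config)
  model <- config$model
  m <- config$m
  genomes <- states$tree$tip.label
  n <- length(genomes)
  ## junction randomness (seed continues from simulate_states)
  db <- matrix(stats::runif((m - 1L) * n) < config$double_break_rate,
               max(m - 1L, 0L), n)
  flip_p <- matrix(model$theta, max(m - 1L, 0L), n)
  flip_p[db] <- 0.5
  flips <- matrix(stats::runif((m - 1L) * n), max(m - 1L, 0L), n) < flip_p
  v <- matrix(0L, m, n)
  v[1L, ] <- sample(1:2, n, replace = TRUE)
  if (m > 1L) for (i in 2:m)
    v[i, ] <- ifelse(flips[i - 1L, ], 3L - v[i - 1L, ], v[i - 1L, ])
  ts <- states$tip_states
  ## observation: U/F -> duplicated; S1 single in slot p1 iff v = 1; S2 mirrored
  obs <- matrix(OBS_DUPLICATED, m, n)
  obs[ts == 3L] <- ifelse(v[ts == 3L] == 1L, OBS_SINGLE_P1, OBS_SINGLE_P2)
  obs[ts == 4L] <- ifelse(v[ts == 4L] == 1L, OBS_SINGLE_P2, OBS_SINGLE_P1)
  colnames(obs) <- genomes
  anchors <- sprintf("anc%05d", seq_len(m))
  ## gene ids record the true parental subgenome: <genome>_s<sub>_<pillar>
  gid <- function(g, sub, i) sprintf("%s_s%d_%05d", genomes[g], sub, i)
  p1 <- p2 <- matrix(NA_character_, m, n, dimnames = list(NULL, genomes))
  for (g in seq_len(n)) {
    dup <- ts[, g] <= 2L
    i <- seq_len(m)
    sub1 <- v[, g]        # subgenome occupying slot p1
    sub2 <- 3L - v[, g]
    p1[dup, g] <- gid(g, sub1[dup], i[dup])
    p2[dup, g] <- gid(g, sub2[dup], i[dup])
    s1 <- ts[, g] == 3L   # subgenome-1 copy survives
    s2 <- ts[, g] == 4L
    slot1 <- (s1 & v[, g] == 1L) | (s2 & v[, g] == 2L)
    slot2 <- (s1 & v[, g] == 2L) | (s2 & v[, g] == 1L)
    p1[slot1, g] <- gid(g, ifelse(s1[slot1], 1L, 2L), i[slot1])
    p2[slot2, g] <- gid(g, ifelse(s1[slot2], 1L, 2L), i[slot2])
  }
  pillar_set(obs, genomes = genomes, anchors = anchors, double_break = db,
             genes = list(p1 = p1, p2 = p2),
             truth = list(assignment = v, tip_states = ts,
                          realized_counts = states$realized_counts,
                          config = config))
}

#' Emit genome annotations and homology candidates for a simulated dataset
#'
#' Converts a simulated pillar set into the raw inputs of the synteny
#' pipeline: per-genome gene orders (each genome carries two homoeologous
#' chromosomes, one per parental subgenome, holding its surviving genes in
#' ancestral pillar order, plus a single outgroup chromosome of anchor
#' genes) and an anchor-to-candidate homology table whose quality columns
#' pass the default homolog filters.
#'
#' @param pillars a [simulate_pillars()] result (gene ids encode the truth).
#' @param outgroup name for the outgroup genome (default `"out"`).
#' @return List with `gene_orders` (data frame: `genome`, `chromosome`,
#'   `position`, `gene_id`) and `homologs` (data frame: `outgroup_gene`,
#'   `genome`, `candidate_gene`, `identity`, `len_ratio`,
#'   `seven_mer_count`, `evalue`, `ka`).
#' @export
simulate_genome_orders <- function(pillars, outgroup = "out") {
  stopifnot(inherits(pillars, "pillar_set"), !is.null(pillars$genes))
  genomes <- pillars$genomes
  m <- n_pillars(pillars)
  orders <- list(data.frame(genome = outgroup, chromosome = "chr0",
                            position = seq_len(m), gene_id = pillars$anchors))
  homologs <- list()
  for (g in seq_along(genomes)) {
    genes <- c(pillars$genes$p1[, g], pillars$genes$p2[, g])
    anch <- rep(pillars$anchors, 2L)
    pos <- rep(seq_len(m), 2L)
    keep <- !is.na(genes)
    genes <- genes[keep]; anch <- anch[keep]; pos <- pos[keep]
    sub <- as.integer(sub(".*_s([12])_.*", "\\1", genes))
    ord <- order(sub, pos)
    orders[[g + 1L]] <- data.frame(genome = genomes[g],
                                   chromosome = paste0("chr", sub[ord]),
                                   position = seq_along(ord),
                                   gene_id = genes[ord])
    homologs[[g]] <- data.frame(outgroup_gene = anch, genome = genomes[g],
                                candidate_gene = genes, identity = 0.9,
                                len_ratio = 0.95, seven_mer_count = 5L,
                                evalue = 1e-50, ka = 0.05)
  }
  list(gene_orders = do.call(rbind, orders),
       homologs = do.call(rbind, homologs))
}

#' Simulate a protein-interaction edge list over single-copy genes
#'
#' Draws undirected edges between single-copy genes carrying known
#' subgenome labels, down-weighting edges that cross subgenomes by the
#' factor `crossing_depletion` (1 = uniform random pairing, 0 = no crossing
#' edges at all). Used to exercise the interaction-network tests with a
#' known effect size.
#'
#' @param labels named integer vector (values 1/2): the subgenome of origin
#'   of each single-copy gene.
#' @param n_edges number of distinct edges to draw.
#' @param crossing_depletion acceptance probability of a cross-subgenome
#'   pair relative to a same-subgenome pair, in `[0, 1]`.
#' @param seed integer seed.
#' @return Data frame with columns `gene_a`, `gene_b`.
#' @export
simulate_interaction_network <- function(labels, n_edges, crossing_depletion = 1,
                                         seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(crossing_depletion >= 0, crossing_depletion <= 1)
  genes <- names(labels)
  if (is.null(genes) || length(genes) < 2L)
    stop("`labels` must be a named vector over at least two genes", call. = FALSE)
  set.seed(as.integer(seed))
  seen <- character(0)
  a <- b <- character(n_edges)
  k <- 0L
  while (k < n_edges) {
    i <- sample.int(length(genes), 2L)
    cross <- labels[i[1L]] != labels[i[2L]]
    if (cross && stats::runif(1) > crossing_depletion) next
    key <- paste(sort(genes[i]), collapse = "\r")
    if (key %in% seen) next
    k <- k + 1L
    seen <- c(seen, key)
    a[k] <- genes[i[1L]]; b[k] <- genes[i[2L]]
  }
  data.frame(gene_a = a, gene_b = b)
}
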