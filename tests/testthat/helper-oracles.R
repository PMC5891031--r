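# Independent oracles and small fixture builders used across the suite.

# Brute-force total log-likelihood of the assignment-vector HMM: explicit
# enumeration of all S^m hidden paths (S = 2^n). Emissions come from
# pillar_loglik (plain R pruning), transitions from junction_transition.
brute_force_loglik <- function(pillars, model) {
  n <- n_genomes(pillars)
  m <- n_pillars(pillars)
  S <- 2^n
  vecs <- assignment_vectors(pillars$genomes)
  em <- matrix(0, m, S)
  for (i in seq_len(m)) for (j in seq_len(S))
    em[i, j] <- exp(pillar_loglik(pillars, i, vecs[j, ], model))
  Ks <- if (m > 1) lapply(seq_len(m - 1), function(i) junction_transition(pillars, model, i))
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), m)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    pr <- (1 / S) * em[1, paths[r, 1]]
    if (m > 1) for (i in 2:m)
      pr <- pr * Ks[[i - 1]][paths[r, i - 1], paths[r, i]] * em[i, paths[r, i]]
    total <- total + pr
  }
  log(total)
}

# Brute-force per-pillar posterior over assignment vectors by the same path
# enumeration.
brute_force_posterior <- function(pillars, model) {
  n <- n_genomes(pillars)
  m <- n_pillars(pillars)
  S <- 2^n
  vecs <- assignment_vectors(pillars$genomes)
  em <- matrix(0, m, S)
  for (i in seq_len(m)) for (j in seq_len(S))
    em[i, j] <- exp(pillar_loglik(pillars, i, vecs[j, ], model))
  Ks <- if (m > 1) lapply(seq_len(m - 1), function(i) junction_transition(pillars, model, i))
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), m)))
  w <- numeric(nrow(paths))
  for (r in seq_len(nrow(paths))) {
    pr <- (1 / S) * em[1, paths[r, 1]]
    if (m > 1) for (i in 2:m)
      pr <- pr * Ks[[i - 1]][paths[r, i - 1], paths[r, i]] * em[i, paths[r, i]]
    w[r] <- pr
  }
  w <- w / sum(w)
  post <- matrix(0, m, S)
  for (i in seq_len(m)) for (j in seq_len(S))
    post[i, j] <- sum(w[paths[, i] == j])
  post
}

# All permutations of 1..n (for exhaustive annealing oracles).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) for (k in seq_len(n))
    out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

# Independent re-statement of the synteny chain score: number of adjacent
# (code difference exactly 1) consecutive non-empty positions.
chain_score_oracle <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) < 2L) 0L else sum(abs(diff(v)) == 1)
}

lookup_codes <- function(genes, codes) {
  out <- rep(NA_real_, length(genes))
  out[!is.na(genes)] <- unname(codes[genes[!is.na(genes)]])
  out
}

# A deterministic little two-genome pillar set with mixed observations.
toy_pillars <- function(m = 3, seed = 1, genomes = c("gA", "gB"),
                        double_break = NULL) {
  set.seed(seed)
  obs <- matrix(sample(1:3, m * length(genomes), replace = TRUE), m,
                dimnames = list(NULL, genomes))
  pillar_set(obs, double_break = double_break)
}

toy_tree2 <- function() ape::read.tree(text = "(gA:0.4,gB:0.6);")

# Tiny single-chromosome annotation: genes in the given left-to-right order.
toy_orders <- function(genes, genome = "g1", chromosome = "c1") {
  data.frame(genome = genome, chromosome = chromosome,
             position = seq_along(genes), gene_id = genes)
}
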