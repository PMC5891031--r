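test_that("tip likelihoods encode the observation semantics", {
  expect_equal(unname(tip_likelihood("duplicated", 1)), c(1, 1, 0, 0))
  expect_equal(unname(tip_likelihood("duplicated", 2)), c(1, 1, 0, 0))
  expect_equal(unname(tip_likelihood("single_in_p1", 1)), c(0, 0, 1, 0))
  expect_equal(unname(tip_likelihood("single_in_p1", 2)), c(0, 0, 0, 1))
  expect_equal(unname(tip_likelihood("single_in_p2", 1)), c(0, 0, 0, 1))
  expect_equal(unname(tip_likelihood("single_in_p2", 2)), c(0, 0, 1, 0))
  expect_error(tip_likelihood("nonsense", 1), "observation")
})

test_that("single-genome pillar likelihoods match the closed form", {
  tr <- ape::read.tree(text = "(g1:0.37);")
  mod <- loss_model(tr, gamma = 0.25, epsilon = 0.6, theta = 0.01)
  P <- loss_transition_probs(0.25, 0.6, 0.37)
  dup <- pillar_set(matrix(1L, 1, 1, dimnames = list(NULL, "g1")))
  expect_equal(pillar_loglik(dup, 1, 1, mod), log(P["U", "U"] + P["U", "F"]))
  s1 <- pillar_set(matrix(2L, 1, 1, dimnames = list(NULL, "g1")))
  expect_equal(pillar_loglik(s1, 1, 1, mod), log(P["U", "S1"]))
  expect_equal(pillar_loglik(s1, 1, 2, mod), log(P["U", "S2"]))
})

test_that("epsilon = 1 makes assignments and their complements equivalent", {
  tr <- ape::read.tree(text = "((gA:0.3,gB:0.5):0.2,gC:0.6);")
  mod <- loss_model(tr, gamma = 0.2, epsilon = 1, theta = 0.01)
  ps <- toy_pillars(m = 5, seed = 3, genomes = c("gA", "gB", "gC"))
  for (i in 1:5) for (v in list(c(1, 1, 1), c(1, 2, 1), c(2, 2, 1))) {
    expect_equal(pillar_loglik(ps, i, v, mod),
                 pillar_loglik(ps, i, 3 - v, mod), tolerance = 1e-12)
  }
  ## and not equivalent once epsilon < 1 (asymmetric data)
  mod2 <- loss_model(tr, gamma = 0.2, epsilon = 0.4, theta = 0.01)
  s1 <- pillar_set(matrix(2L, 1, 3, dimnames = list(NULL, c("gA", "gB", "gC"))))
  expect_gt(abs(pillar_loglik(s1, 1, c(1, 1, 1), mod2) -
                  pillar_loglik(s1, 1, c(2, 2, 2), mod2)), 0.1)
})

test_that("junction kernel factorises over genomes", {
  ps <- toy_pillars(m = 3, seed = 1)
  mod0 <- loss_model(toy_tree2(), theta = 0)
  expect_equal(junction_transition(ps, mod0, 1), diag(4))

  mod <- loss_model(toy_tree2(), theta = 0.01)
  K <- junction_transition(ps, mod, 1)
  expect_equal(unname(diag(K)), rep(0.9801, 4), tolerance = 1e-12)
  expect_equal(rowSums(K), rep(1, 4), ignore_attr = TRUE)

  ## a double break overrides theta with a fair coin for that genome
  db <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  psb <- toy_pillars(m = 3, seed = 1, double_break = db)
  Kb <- junction_transition(psb, mod, 1)
  ## genome gA flips with 0.5: marginal over its bit is uniform
  expect_equal(Kb[1, 1] + Kb[1, 2], Kb[1, 3] + Kb[1, 4] + 0.98, tolerance = 1e-9)
  expect_equal(unname(Kb[1, 2] / (Kb[1, 1] + Kb[1, 2])), 0.5, tolerance = 1e-12)
})

test_that("forward likelihood equals brute-force path enumeration", {
  tr <- toy_tree2()
  mod <- loss_model(tr, gamma = 0.3, epsilon = 0.55, theta = 0.05)
  ps <- toy_pillars(m = 3, seed = 7)
  expect_equal(sequence_loglik(ps, mod), brute_force_loglik(ps, mod),
               tolerance = 1e-9)
  ## with a double break in one genome
  db <- matrix(c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE), 3, 2)
  psb <- toy_pillars(m = 4, seed = 9, double_break = db)
  expect_equal(sequence_loglik(psb, mod), brute_force_loglik(psb, mod),
               tolerance = 1e-9)
})

test_that("degenerate junctions decouple the chain", {
  tr <- toy_tree2()
  mod <- loss_model(tr, gamma = 0.1, epsilon = 0.7, theta = 0.2)
  m <- 4
  db <- matrix(TRUE, m - 1, 2)
  ps <- toy_pillars(m = m, seed = 11, double_break = db)
  vecs <- assignment_vectors(ps$genomes)
  per_pillar <- vapply(seq_len(m), function(i) {
    log(mean(vapply(seq_len(4), function(j)
      exp(pillar_loglik(ps, i, vecs[j, ], mod)), 0)))
  }, 0)
  expect_equal(sequence_loglik(ps, mod), sum(per_pillar), tolerance = 1e-9)
  ## single pillar: log of the uniform mixture
  p1 <- ps[1]
  expect_equal(sequence_loglik(p1, mod), per_pillar[1], tolerance = 1e-9)
})

test_that("likelihood is invariant under reversal of the pillar order", {
  ## forward and backward recursions agree because the flip kernel is
  ## symmetric and the initial distribution uniform
  tr <- ape::read.tree(text = "((gA:0.3,gB:0.5):0.2,gC:0.6);")
  mod <- loss_model(tr, gamma = 0.2, epsilon = 0.5, theta = 0.03)
  set.seed(5)
  obs <- matrix(sample(1:3, 24, replace = TRUE), 8, 3,
                dimnames = list(NULL, c("gA", "gB", "gC")))
  db <- matrix(runif(21) < 0.2, 7, 3)
  ps <- pillar_set(obs, double_break = db)
  rev_ps <- pillar_set(obs[8:1, ], double_break = db[7:1, , drop = FALSE])
  expect_equal(sequence_loglik(ps, mod), sequence_loglik(rev_ps, mod),
               tolerance = 1e-9)
})

test_that("posterior decoding matches brute force and is coherent", {
  tr <- toy_tree2()
  mod <- loss_model(tr, gamma = 0.3, epsilon = 0.55, theta = 0.05)
  ps <- toy_pillars(m = 3, seed = 7)
  post <- posterior_assignments(ps, mod)
  expect_equal(rowSums(post$prob), rep(1, 3), tolerance = 1e-12)
  bf <- brute_force_posterior(ps, mod)
  expect_equal(unname(post$prob), bf, tolerance = 1e-9)
  ## per-genome marginals of subgenome 1 and 2 sum to one
  expect_true(all(post$marginal1 >= 0 & post$marginal1 <= 1))
  marg2 <- post$prob %*% (post$vectors == 2L)
  expect_equal(unname(post$marginal1 + marg2),
               matrix(1, 3, 2), tolerance = 1e-12)
})

test_that("symmetric model gives symmetric posteriors; uninformative pillar uniform", {
  tr <- toy_tree2()
  mod <- loss_model(tr, gamma = 0.2, epsilon = 1, theta = 0.05)
  ps <- toy_pillars(m = 4, seed = 13)
  post <- posterior_assignments(ps, mod)
  S <- 4
  compl <- S:1  # complement of vector j is S + 1 - j in bit order
  expect_equal(post$prob, post$prob[, compl], tolerance = 1e-10)

  ## all genomes duplicated, isolated by double breaks on both sides
  obs <- matrix(1L, 3, 2, dimnames = list(NULL, c("gA", "gB")))
  db <- matrix(TRUE, 2, 2)
  iso <- pillar_set(obs, double_break = db)
  mod2 <- loss_model(toy_tree2(), gamma = 0.2, epsilon = 0.5, theta = 0.05)
  post2 <- posterior_assignments(iso, mod2)
  expect_equal(unname(post2$prob[2, ]), rep(0.25, 4), tolerance = 1e-10)
})

test_that("expected loss counts match hand enumeration on a cherry", {
  b <- 0.45; cc <- 0.3
  ## two-tip star whose root is the WGD; epsilon = 0 pins v = (1,1)
  tr2 <- ape::read.tree(text = sprintf("(gA:%g,gB:%g);", b, b))
  mod <- loss_model(tr2, gamma = 0, epsilon = 0, theta = 0.01)
  obs <- matrix(2L, 1, 2, dimnames = list(NULL, c("gA", "gB")))
  ps <- pillar_set(obs)
  counts <- expected_loss_counts(ps, mod)
  ## both tips lost independently on their own branches: one loss each
  expect_equal(counts$n_to_S1[counts$label == "gA"], 1, tolerance = 1e-9)
  expect_equal(counts$n_to_S1[counts$label == "gB"], 1, tolerance = 1e-9)
  expect_equal(sum(counts$n_to_S2), 0, tolerance = 1e-12)

  ## cherry with a shared internal branch: losses can be shared
  tr3 <- ape::read.tree(text = sprintf("((gA:%g,gB:%g):%g,gC:0.9);", b, b, cc))
  mod3 <- loss_model(tr3, gamma = 0, epsilon = 0, theta = 0.01)
  obs3 <- matrix(c(2L, 2L, 1L), 1, 3, dimnames = list(NULL, c("gA", "gB", "gC")))
  ps3 <- pillar_set(obs3)
  counts3 <- expected_loss_counts(ps3, mod3)
  ## hand enumeration over the state of the cherry ancestor (U or S1);
  ## gC duplicated keeps the root in U w.p. 1 on its own branch
  P1 <- loss_transition_probs(0, 0, b)["U", "S1"]
  PUU <- loss_transition_probs(0, 0, cc)["U", "U"]
  PUS <- loss_transition_probs(0, 0, cc)["U", "S1"]
  w_shared <- PUS * 1 * 1
  w_indep <- PUU * P1 * P1
  z <- w_shared + w_indep
  shared_edge <- counts3$edge[counts3$label == "node5"]
  expect_equal(counts3$n_to_S1[counts3$edge == shared_edge], w_shared / z,
               tolerance = 1e-9)
  expect_equal(counts3$n_to_S1[counts3$label == "gA"], w_indep / z,
               tolerance = 1e-9)
  ## every single-copy observation is accounted for by exactly the right
  ## total number of loss events (shared losses counted once)
  expect_equal(sum(counts3$n_to_S1),
               w_shared / z * 1 + w_indep / z * 2, tolerance = 1e-9)
})

test_that("realized simulation counts match posterior expectations", {
  tr <- ape::read.tree(text = "((g1:0.3,g2:0.4):0.3,g3:0.6);")
  cfg <- wgd_sim_config(tree = tr, m = 2000, gamma = 0.15, epsilon = 0.6,
                        theta = 0.01, double_break_rate = 0.02, seed = 31)
  ps <- simulate_pillars(cfg)
  counts <- expected_loss_counts(ps, cfg$model)
  truth <- ps$truth$realized_counts
  for (e in seq_len(nrow(counts))) {
    for (col in c("n_to_S1", "n_to_S2")) {
      exp_n <- counts[[col]][e]; real_n <- truth[[col]][e]
      ## Monte-Carlo tolerance: a few sigma of a binomial count
      expect_lt(abs(exp_n - real_n), 4 * sqrt(max(real_n, 20)))
    }
  }
})

test_that("block segmentation follows the run-length rules", {
  mk_post <- function(marg1) {
    structure(list(marginal1 = marg1), class = "wgd_posterior")
  }
  m <- 6; n <- 3
  ps <- pillar_set(matrix(1L, m, n, dimnames = list(NULL, paste0("g", 1:n))))
  ## all confident, same assignment: one block
  post <- mk_post(matrix(0.95, m, n))
  expect_equal(nrow(block_segmentation(post, ps)), 1L)
  ## one flip mid-sequence: exactly two blocks
  marg <- matrix(0.95, m, n); marg[4:6, ] <- 0.05
  bl <- block_segmentation(mk_post(marg), ps)
  expect_equal(bl$start, c(1L, 4L))
  expect_equal(bl$end, c(3L, 6L))
  ## confidence dipping below 0.85 for enough genomes cuts blocks there
  marg2 <- matrix(0.95, m, n)
  marg2[3, 1:2] <- 0.6   # with min_genomes = 2, junctions 2 and 3 fail
  bl2 <- block_segmentation(mk_post(marg2), ps, min_genomes = 2)
  expect_equal(bl2$start, c(1L, 3L, 4L))
  ## an all-genome double break always terminates
  db <- matrix(FALSE, m - 1, n); db[2, ] <- TRUE
  psb <- pillar_set(matrix(1L, m, n, dimnames = list(NULL, paste0("g", 1:n))),
                    double_break = db)
  bl3 <- block_segmentation(mk_post(matrix(0.95, m, n)), psb)
  expect_equal(bl3$start, c(1L, 3L))
  expect_error(block_segmentation(post, ps, min_genomes = 4), "min_genomes")
})

test_that("posterior mass on the true assignment grows as theta shrinks", {
  tr <- ape::read.tree(text = "(((g1:0.3,g2:0.3):0.2,g3:0.5):0.2,g4:0.6);")
  mean_true_mass <- vapply(c(0.2, 0.05, 0.005), function(th) {
    cfg <- wgd_sim_config(tree = tr, m = 400, gamma = 0.15, epsilon = 0.6,
                          theta = th, double_break_rate = 0, seed = 77)
    ps <- simulate_pillars(cfg)
    post <- posterior_assignments(ps, cfg$model)
    vt <- ps$truth$assignment
    idx <- 1L + as.integer((vt == 2L) %*% 2L^(seq_len(ncol(vt)) - 1L))
    mean(post$prob[cbind(seq_len(nrow(vt)), idx)])
  }, 0)
  expect_true(all(diff(mean_true_mass) > 0))
})
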