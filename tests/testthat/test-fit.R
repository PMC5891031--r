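fake_fit <- function(logLik, df) {
  structure(list(logLik = logLik, df = df), class = "wgd_fit")
}

test_that("likelihood ratio test: statistic and chi-square tail", {
  out <- lrt(fake_fit(-100, 5), fake_fit(-100, 6))
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  ## canonical 5% critical value of chi-square with 1 df
  out2 <- lrt(fake_fit(-100, 5), fake_fit(-100 + 3.8415 / 2, 6))
  expect_equal(round(out2$p_value, 4), 0.0500)
  expect_error(lrt(fake_fit(-100, 5), fake_fit(-101, 6)), "optimisation")
  expect_error(lrt(fake_fit(-100, 6), fake_fit(-100, 6)), "free parameters")
})

test_that("model families are nested in likelihood", {
  tr <- ape::read.tree(text = "((g1:0.3,g2:0.4):0.3,g3:0.6);")
  cfg <- wgd_sim_config(tree = tr, m = 250, gamma = 0.2, epsilon = 0.6,
                        theta = 0.01, seed = 4)
  ps <- simulate_pillars(cfg)
  fits <- lapply(c("n", "f", "bf"), function(fam)
    fit_model(ps, tr, family = fam, seed = 1))
  expect_true(fits[[2]]$logLik >= fits[[1]]$logLik - 0.01)
  expect_true(fits[[3]]$logLik >= fits[[2]]$logLik - 0.01)
  ## same seed, same data: bit-identical refit
  refit <- fit_model(ps, tr, family = "bf", seed = 1)
  expect_identical(refit$logLik, fits[[3]]$logLik)
  expect_identical(refit$branch_lengths, fits[[3]]$branch_lengths)
})

test_that("random restarts agree on the maximised likelihood", {
  tr <- ape::read.tree(text = "((g1:0.3,g2:0.4):0.3,g3:0.6);")
  cfg <- wgd_sim_config(tree = tr, m = 800, gamma = 0.2, epsilon = 0.6,
                        theta = 0.01, seed = 6)
  ps <- simulate_pillars(cfg)
  ## five random starting points at the optimiser's own restart scale
  lls <- vapply(1:5, function(s) {
    set.seed(s)
    tr_s <- tr
    tr_s$edge.length <- rep(0.3, nrow(tr$edge)) * exp(rnorm(nrow(tr$edge), 0, 0.5))
    fit_model(ps, tr_s, family = "bf", seed = s,
              init = list(gamma = 0.1 * exp(rnorm(1, 0, 0.5)),
                          epsilon = min(0.7 * exp(rnorm(1, 0, 0.3)), 1),
                          theta = 0.01 * exp(rnorm(1, 0, 0.5))))$logLik
  }, 0)
  expect_lt(max(lls) - min(lls), 0.01)
})

test_that("epsilon pegs at the boundary on unbiased data", {
  tr <- ape::read.tree(text = "((g1:0.3,g2:0.4):0.3,g3:0.6);")
  cfg <- wgd_sim_config(tree = tr, m = 400, gamma = 0.15, epsilon = 1,
                        theta = 0.01, seed = 8)
  ps <- simulate_pillars(cfg)
  fit <- fit_model(ps, tr, family = "bf", seed = 2)
  expect_gt(fit$epsilon, 0.9)
})

test_that("topology sweep enumerates rooted topologies and caps taxa", {
  tr <- ape::read.tree(text = "((g1:0.3,g2:0.4):0.3,g3:0.6);")
  cfg <- wgd_sim_config(tree = tr, m = 60, gamma = 0.2, epsilon = 0.6,
                        theta = 0.01, seed = 14)
  ps <- simulate_pillars(cfg)
  sw <- topology_sweep(ps, family = "f", seed = 1)
  expect_equal(nrow(sw$results), 3L)  # three rooted topologies on three taxa
  expect_true(all(diff(sw$results$logLik) <= 1e-8))
  expect_error(topology_sweep(ps, max_taxa = 2L), "capped")
})

test_that("per-block epsilon refits find planted heterogeneity", {
  tr <- ape::read.tree(text = "((g1:0.35,g2:0.45):0.3,g3:0.7);")
  cfg1 <- wgd_sim_config(tree = tr, m = 400, gamma = 0.15, epsilon = 0.35,
                         theta = 0.01, seed = 21)
  cfg2 <- wgd_sim_config(tree = tr, m = 400, gamma = 0.15, epsilon = 1,
                         theta = 0.01, seed = 22)
  p1 <- simulate_pillars(cfg1); p2 <- simulate_pillars(cfg2)
  obs <- rbind(p1$obs, p2$obs)
  ps <- pillar_set(obs, genomes = p1$genomes)
  fit <- fit_model(ps, tr, family = "bf", seed = 3)
  blocks <- data.frame(block = 1:4, start = c(1, 201, 401, 601),
                       end = c(200, 400, 600, 800),
                       n_pillars = c(200, 200, 200, 200))
  be <- fit_blocks(ps, blocks, fit, min_pillars = 150)
  ## the two epsilon = 1 blocks rank above the two biased ones
  expect_true(min(be$epsilon[3:4]) > max(be$epsilon[1:2]))
  ## a block below the minimum size is absent from the output
  blocks2 <- rbind(blocks, data.frame(block = 5, start = 1, end = 100,
                                      n_pillars = 100))
  expect_message(be2 <- fit_blocks(ps, blocks2, fit, min_pillars = 150),
                 "skipped")
  expect_false(5 %in% be2$block)
})
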