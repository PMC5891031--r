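# A little world with one genome, one or two chromosomes, where truth is a
# fully collinear duplicated layout: anchors a1..am, slot-1 genes x1..xm on
# chromosome c1, slot-2 genes y1..ym on c2.
collinear_world <- function(m, genome = "g1") {
  list(anchors = sprintf("a%02d", 1:m),
       x = sprintf("x%02d", 1:m), y = sprintf("y%02d", 1:m),
       orders = rbind(toy_orders(sprintf("x%02d", 1:m), genome, "c1"),
                      toy_orders(sprintf("y%02d", 1:m), genome, "c2")),
       genome = genome)
}

test_that("homolog pair filters apply the published thresholds", {
  pairs <- data.frame(
    identity = c(1.00, 0.60, 0.90, 0.65, 0.95),
    len_ratio = c(1.00, 1.00, 0.75, 0.95, 0.90),
    seven_mer_count = c(94, 30, 10, 5, 2),
    evalue = c(0, 1e-40, 1e-30, 1e-4, 1e-12),
    ka = c(0.01, 0.02, 0.05, 0.08, 0.30))
  seed <- filter_homolog_pairs(pairs, mode = "seed")
  expect_equal(rownames(seed), "1")       # identity/ratio/7-mer rules
  blast <- filter_homolog_pairs(pairs, mode = "blast")
  expect_equal(rownames(blast), "1")      # row 4 fails the E-value cutoff
  ## Ka cutoff configurable (0.2 admits the slower-evolving outgroup pair)
  pairs$ka[1] <- 0.15
  expect_equal(nrow(filter_homolog_pairs(pairs, mode = "seed")), 0L)
  expect_equal(nrow(filter_homolog_pairs(pairs, mode = "seed", max_ka = 0.2)), 1L)
  expect_error(filter_homolog_pairs(pairs[, c("identity", "len_ratio")],
                                    mode = "seed"), "seven_mer_count")
  ## identical sequences share many 7-mers
  s <- paste(rep("MKVLITAGPT", 10), collapse = "")
  expect_gte(count_shared_kmers(s, s), 2L)
  expect_equal(count_shared_kmers("MKVLITA", "AAAAAAA"), 0L)
})

test_that("synteny score counts neighbor links per slot chain", {
  w <- collinear_world(5)
  full <- dcs_candidates(w$anchors, Map(c, w$x, w$y), w$genome,
                         assign = cbind(w$x, w$y))
  ## 3 pillars, both slots collinear: 2 junctions x 2 slots = 4
  three <- dcs_candidates(w$anchors[1:3], Map(c, w$x[1:3], w$y[1:3]), w$genome,
                          assign = cbind(w$x[1:3], w$y[1:3]))
  expect_equal(synteny_score(three, w$orders), 4L)
  ## slot-2 empty, slot-1 collinear over 5 pillars: 4
  p1only <- dcs_candidates(w$anchors, as.list(w$x), w$genome,
                           assign = cbind(w$x, NA))
  expect_equal(synteny_score(p1only, w$orders), 4L)
  ## no assignments at all
  none <- dcs_candidates(w$anchors, as.list(w$x), w$genome,
                         assign = cbind(NA, NA)[rep(1, 5), ])
  expect_equal(synteny_score(none, w$orders), 0L)
  ## full two-slot score, and order reversal leaves it unchanged
  expect_equal(synteny_score(full, w$orders), 8L)
  expect_equal(synteny_score(full, w$orders, order = 5:1), 8L)
})

test_that("break detection distinguishes single and double breaks", {
  m <- 6
  w <- collinear_world(m)
  ps <- pillar_set(matrix(1L, m, 1, dimnames = list(NULL, w$genome)),
                   anchors = w$anchors,
                   genes = list(p1 = matrix(w$x, m, 1), p2 = matrix(w$y, m, 1)))
  br <- detect_breaks(ps, w$orders)
  expect_equal(br$n_breaks, 0L)
  expect_equal(br$n_double_breaks, 0L)

  ## both chromosomes split between pillars 3 and 4: one double break at 3
  split_orders <- rbind(
    toy_orders(w$x[1:3], w$genome, "c1a"), toy_orders(w$x[4:6], w$genome, "c1b"),
    toy_orders(w$y[1:3], w$genome, "c2a"), toy_orders(w$y[4:6], w$genome, "c2b"))
  br2 <- detect_breaks(ps, split_orders)
  expect_equal(br2$n_breaks, 2L)
  expect_equal(br2$n_double_breaks, 1L)
  expect_true(br2$double_break[3, 1])
  expect_identical(br2$pillars$double_break, br2$double_break)

  ## slot-1 intact but slot-2 gene translocated: single break, not double
  trans_orders <- rbind(
    toy_orders(w$x, w$genome, "c1"),
    toy_orders(c(w$y[1:3], w$y[5], w$y[4], w$y[6]), w$genome, "c2"))
  br3 <- detect_breaks(ps, trans_orders)
  expect_equal(br3$n_double_breaks, 0L)
  expect_gt(br3$n_breaks, 0L)
})

test_that("annealing keeps an optimal configuration and is deterministic", {
  m <- 5
  w <- collinear_world(m)
  opt <- dcs_candidates(w$anchors, Map(c, w$x, w$y), w$genome,
                        assign = cbind(w$x, w$y))
  a <- anneal_pillars(opt, w$orders, seed = 1, t0 = 0.02, t_min = 0.01,
                      moves_per_temp = 50, quench_sweeps = 10)
  expect_equal(a$score, 2L * (m - 1L))  # stays at the optimum
  b <- anneal_pillars(opt, w$orders, seed = 1, t0 = 0.02, t_min = 0.01,
                      moves_per_temp = 50, quench_sweeps = 10)
  expect_identical(a$order, b$order)
  expect_identical(a$cand$assign, b$cand$assign)
  expect_error(anneal_pillars(opt, w$orders, seed = 1, t0 = 0.01, t_min = 0.02),
               "t0 > t_min")
  expect_error(dcs_candidates(w$anchors, rep(list(character(0)), m), w$genome),
               "empty candidate")
})

test_that("running score stays consistent with full recomputation", {
  ## random instance with decoy candidates; the annealer validates its
  ## incremental score against a full recount at checkpoints and on exit
  m <- 10
  w <- collinear_world(m)
  set.seed(42)
  decoys <- sprintf("d%02d", 1:m)
  orders <- rbind(w$orders, toy_orders(decoys, w$genome, "c3"))
  cands <- Map(function(x, y, d) sample(c(x, y, d)), w$x, w$y, decoys)
  cand <- dcs_candidates(w$anchors, cands, w$genome)
  a <- anneal_pillars(cand, orders, seed = 7, t0 = 1, t_min = 0.05,
                      moves_per_temp = 60, validate_every = 5)
  final <- dcs_candidates(a$cand$anchors, a$cand$candidates, w$genome,
                          assign = a$cand$assign)
  expect_equal(a$score, synteny_score(final, orders, order = a$order))
})

test_that("merge keeps only supported genes and fully covered pillars", {
  m <- 4
  wa <- collinear_world(m, "gA")
  wb <- collinear_world(m, "gB")
  wb$orders$gene_id <- sub("^x", "u", sub("^y", "v", wb$orders$gene_id))
  ub <- sub("^x", "u", wb$x); vb <- sub("^y", "v", wb$y)
  ca <- dcs_candidates(wa$anchors, Map(c, wa$x, wa$y), "gA",
                       assign = cbind(wa$x, wa$y))
  ## genome B misses anchor 3 entirely and has one unsupported gene:
  ## v4 is moved to its own chromosome, away from every other gene
  assign_b <- cbind(ub, vb); assign_b[3, ] <- NA
  orders_b <- wb$orders[wb$orders$gene_id != "v04", ]
  orders_b <- rbind(orders_b, data.frame(genome = "gB", chromosome = "c9",
                                         position = 1, gene_id = "v04"))
  cb <- dcs_candidates(wb$anchors, Map(c, ub, vb), "gB", assign = assign_b)
  merged <- merge_pillars(list(gA = ca, gB = cb), rbind(wa$orders, orders_b))
  ## pillar 3 dropped (no gB gene). v04 is unsupported (its only neighbors
  ## are off on c9), and u04's sole neighbor u03 is unassigned, so pillar 4
  ## loses both gB genes and is dropped too
  expect_equal(merged$anchors, wa$anchors[1:2])
  expect_false("v04" %in% merged$genes$p2[, "gB"])
  ## identical fully supported sets merge to themselves
  same <- merge_pillars(list(gA = ca), wa$orders)
  expect_equal(same$anchors, wa$anchors)
  expect_equal(same$genes$p1[, 1], wa$x, ignore_attr = TRUE)
  cb_bad <- dcs_candidates(rev(wb$anchors), rev(Map(c, ub, vb)), "gB")
  expect_error(merge_pillars(list(gA = ca, gB = cb_bad), wa$orders), "anchors")
})

test_that("high-synteny subset requires full support in one direction", {
  m <- 5
  w <- collinear_world(m)
  mk_ps <- function(p2genes) {
    pillar_set(matrix(1L, m, 1, dimnames = list(NULL, w$genome)),
               anchors = w$anchors,
               genes = list(p1 = matrix(w$x, m, 1), p2 = matrix(p2genes, m, 1)))
  }
  ps <- mk_ps(w$y)
  expect_equal(n_pillars(high_synteny_subset(ps, w$orders)), m)
  ## pillar 3's slot-2 gene alone on its own chromosome: unlinked both ways
  orders2 <- w$orders
  orders2$chromosome[orders2$gene_id == "y03"] <- "c9"
  hs <- high_synteny_subset(ps, orders2)
  expect_equal(n_pillars(hs), m - 1L)
  expect_false("a03" %in% hs$anchors)
  ## nothing passes when every slot-2 gene is isolated
  orders3 <- w$orders
  orders3$chromosome[grepl("^y", orders3$gene_id)] <-
    paste0("cy", seq_len(m))
  expect_equal(n_pillars(high_synteny_subset(ps, orders3)), 0L)
})

test_that("optimising the order reduces breaks relative to a scrambled start", {
  tr <- example_wgd_tree(2); tr$edge.length[] <- 1e-9
  cfg <- wgd_sim_config(tree = tr, m = 15, gamma = 0, epsilon = 1, theta = 0,
                        double_break_rate = 0, seed = 12)
  ps <- simulate_pillars(cfg)
  gen <- simulate_genome_orders(ps)
  set.seed(3)
  scramble <- sample(15)
  scrambled_breaks <- detect_breaks(ps, gen$gene_orders, order = scramble)
  res <- optimize_global_order(ps, gen$gene_orders, seed = 4, order = scramble,
                               t0 = 2)
  opt_breaks <- detect_breaks(ps, gen$gene_orders, order = res$best$order)
  expect_gt(res$best$score, res$initial_score)
  expect_lt(opt_breaks$n_breaks, scrambled_breaks$n_breaks)
  expect_lte(opt_breaks$n_double_breaks, scrambled_breaks$n_double_breaks)
})
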