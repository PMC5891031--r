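## Position codes: a gene's (chromosome, rank) within the analysis-set
## restricted order, packed as chrom_index * 1e6 + rank so that two genes
## are genomic neighbors iff their codes differ by exactly 1. Neighborhood
## deliberately ignores genes outside the analysis set.
CODE_BASE <- 1e6

#' Gene position codes within the analysis set
#'
#' Restricts one genome's annotation to the given analysis set, re-ranks
#' genes within each chromosome, and returns a named numeric code per gene
#' such that two genes are genomic neighbors (adjacent within the analysis
#' set on the same chromosome) iff their codes differ by exactly 1.
#'
#' @param gene_orders data frame with columns `genome`, `chromosome`,
#'   `position`, `gene_id` (see [read_gene_orders()]).
#' @param genome genome name to extract.
#' @param analysis_genes character vector of gene ids forming the analysis
#'   set; genes outside it are ignored for the neighbor relation.
#' @return Named numeric vector of codes.
#' @export
gene_codes <- function(gene_orders, genome, analysis_genes) {
  d <- gene_orders[gene_orders$genome == genome &
                     gene_orders$gene_id %in% analysis_genes, , drop = FALSE]
  if (!nrow(d)) return(stats::setNames(numeric(0), character(0)))
  chrom <- factor(d$chromosome)
  rk <- stats::ave(as.numeric(d$position), chrom, FUN = rank)
  if (max(rk) >= CODE_BASE) stop("chromosome too long for position codes", call. = FALSE)
  stats::setNames(as.numeric(chrom) * CODE_BASE + rk, d$gene_id)
}

codes_of <- function(genes, codes) {
  out <- rep(NA_real_, length(genes))
  hit <- !is.na(genes)
  out[hit] <- codes[genes[hit]]
  out
}

## Score of one slot chain: number of consecutive non-empty positions whose
## genes are genomic neighbors. `v` = codes along the pillar order.
chain_score <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) < 2L) 0L else sum(abs(diff(v)) == 1)
}

#' Candidate homolog sets for one polyploid genome
#'
#' The unit of genome-specific synteny inference: for each ancestral
#' (outgroup) anchor gene, the set of candidate homologs from one polyploid
#' genome, of which at most two can occupy the pillar's homoeologous slots
#' `p1` and `p2`. The initial assignment greedily fills both slots with the
#' first unclaimed candidates; one gene can be claimed by at most one slot
#' of one pillar globally.
#'
#' @param anchors character vector of outgroup anchor ids (in outgroup
#'   order).
#' @param candidates list (one element per anchor) of character vectors of
#'   candidate homolog gene ids.
#' @param genome name of the polyploid genome.
#' @param assign optional initial `m` x 2 character assignment matrix.
#' @return Object of class `dcs_candidates`.
#' @export
dcs_candidates <- function(anchors, candidates, genome, assign = NULL) {
  m <- length(anchors)
  stopifnot(length(candidates) == m)
  if (m == 0L || all(lengths(candidates) == 0L))
    stop("empty candidate set", call. = FALSE)
  if (is.null(assign)) {
    assign <- matrix(NA_character_, m, 2L)
    used <- character(0)
    for (i in seq_len(m)) {
      avail <- setdiff(candidates[[i]], used)
      take <- utils::head(avail, 2L)
      if (length(take)) assign[i, seq_along(take)] <- take
      used <- c(used, take)
    }
  } else {
    stopifnot(nrow(assign) == m, ncol(assign) == 2L)
    g <- assign[!is.na(assign)]
    if (anyDuplicated(g)) stop("a gene may occupy at most one slot", call. = FALSE)
  }
  structure(list(anchors = anchors, candidates = candidates,
                 genome = genome, assign = assign),
            class = "dcs_candidates")
}

## Pull the per-genome m x 2 code matrices out of either a dcs_candidates
## or a multi-genome pillar_set (list of one matrix per genome).
code_matrices <- function(x, gene_orders) {
  if (inherits(x, "dcs_candidates")) {
    codes <- gene_codes(gene_orders, x$genome, unique(unlist(x$candidates)))
    list(matrix(codes_of(as.vector(x$assign), codes), ncol = 2L))
  } else if (inherits(x, "pillar_set")) {
    if (is.null(x$genes)) stop("pillar set carries no gene ids", call. = FALSE)
    lapply(seq_along(x$genomes), function(g) {
      genes <- c(x$genes$p1[, g], x$genes$p2[, g])
      codes <- gene_codes(gene_orders, x$genomes[g], unique(genes[!is.na(genes)]))
      matrix(codes_of(genes, codes), ncol = 2L)
    })
  } else stop("`x` must be a dcs_candidates or pillar_set", call. = FALSE)
}

#' Synteny score of a pillar configuration
#'
#' The optimisation criterion of the pillar pipeline: for every pillar
#' position, every homoeologous slot and every genome, one point is scored
#' when the slot's gene and the next non-empty gene in the same slot (under
#' the given pillar order) are genomic neighbors. Empty slots and chain
#' ends contribute nothing; the scan never wraps around.
#'
#' @param x a [dcs_candidates()] (one genome) or a [pillar_set()] with gene
#'   ids (all genomes).
#' @param gene_orders annotation data frame (see [read_gene_orders()]).
#' @param order pillar order as a permutation of `1..m` (default: as given).
#' @return Integer score.
#' @export
synteny_score <- function(x, gene_orders, order = NULL) {
  cms <- code_matrices(x, gene_orders)
  m <- nrow(cms[[1L]])
  if (is.null(order)) order <- seq_len(m)
  s <- 0L
  for (cm in cms) s <- s + chain_score(cm[order, 1L]) + chain_score(cm[order, 2L])
  s
}

#' Synteny break detection
#'
#' Flags, for every pillar position, genome and slot, whether the slot's
#' gene and the next non-empty same-slot gene (under the pillar order) fail
#' to be genomic neighbors; a position where both slots break in the same
#' genome is a double synteny break, at which that genome's subgenome
#' assignment decorrelates. Returns the flags, summary counts, and a copy
#' of the pillar set with its junction double-break flags installed.
#'
#' @inheritParams synteny_score
#' @param x a [pillar_set()] with gene ids.
#' @return List with `slot_breaks` (`m` x `n` x 2 logical), `double_break`
#'   (`(m-1)` x `n` logical), `n_breaks`, `n_double_breaks` and `pillars`.
#' @export
detect_breaks <- function(x, gene_orders, order = NULL) {
  stopifnot(inherits(x, "pillar_set"))
  cms <- code_matrices(x, gene_orders)
  m <- n_pillars(x); n <- length(cms)
  if (is.null(order)) order <- seq_len(m)
  slot_breaks <- array(FALSE, c(m, n, 2L))
  for (g in seq_len(n)) for (k in 1:2) {
    v <- cms[[g]][order, k]
    filled <- which(!is.na(v))
    if (length(filled) > 1L) {
      from <- filled[-length(filled)]
      brk <- abs(v[filled[-1L]] - v[from]) != 1
      slot_breaks[order[from], g, k] <- brk
    }
  }
  ## a double break at order position i decouples junction i -> i+1
  dbl_pos <- slot_breaks[, , 1L, drop = FALSE] & slot_breaks[, , 2L, drop = FALSE]
  dbl_pos <- matrix(dbl_pos, m, n)
  double_break <- matrix(FALSE, max(m - 1L, 0L), n)
  if (m > 1L) double_break[, ] <- dbl_pos[order, , drop = FALSE][-m, , drop = FALSE]
  colnames(double_break) <- x$genomes
  pillars <- x
  ord_obs <- x$obs[order, , drop = FALSE]
  pillars <- pillar_set(ord_obs, genomes = x$genomes, anchors = x$anchors[order],
                        double_break = double_break,
                        genes = if (!is.null(x$genes))
                          list(p1 = x$genes$p1[order, , drop = FALSE],
                               p2 = x$genes$p2[order, , drop = FALSE]),
                        truth = x$truth)
  list(slot_breaks = slot_breaks, double_break = double_break,
       n_breaks = sum(slot_breaks), n_double_breaks = sum(double_break),
       pillars = pillars)
}

## -- simulated annealing ----------------------------------------------------

## local score contribution of pillar `p` (order position known) in one slot
## chain: the links to its previous and next non-empty positions, or the
## bypassing link when `p`'s slot is empty.
local_chain_terms <- function(v_ord, pos) {
  code <- v_ord[pos]
  a <- if (pos > 1L) { w <- which(!is.na(v_ord[seq_len(pos - 1L)])); if (length(w)) v_ord[max(w)] else NA } else NA
  b <- if (pos < length(v_ord)) { w <- which(!is.na(v_ord[(pos + 1L):length(v_ord)])); if (length(w)) v_ord[pos + min(w)] else NA } else NA
  adj <- function(x, y) !is.na(x) && !is.na(y) && abs(x - y) == 1
  if (is.na(code)) as.integer(adj(a, b))
  else as.integer(adj(a, code)) + as.integer(adj(code, b))
}

#' Simulated annealing over pillar assignments and order (one genome)
#'
#' Jointly optimises the homolog-to-slot assignments and the pillar order
#' of one genome's candidate set so as to maximise the synteny score, by
#' Metropolis-accepted random moves under a geometric cooling schedule.
#' Moves: swap two pillars (35%), relocate a segment (15%), reverse a
#' segment (5%), reassign one slot to another unclaimed candidate or empty
#' it (20%), swap a pillar's two slots (10%), and reverse a segment while
#' swapping its slots (15%; an inverted double-conserved-synteny block,
#' which plain moves cannot escape). The score is maintained
#' incrementally (assignment moves update only the affected chain links)
#' and revalidated against a full recomputation at regular checkpoints; the
#' best configuration ever visited is returned.
#'
#' @param cand a [dcs_candidates()] object.
#' @param gene_orders annotation data frame.
#' @param seed integer seed (mandatory; results are reproducible).
#' @param order initial pillar order (default: the outgroup order `1..m`).
#' @param t0,t_min,cooling annealing schedule: temperature starts at `t0`
#'   and is multiplied by `cooling` after every sweep until below `t_min`,
#'   after which `quench_sweeps` hill-climbing sweeps (uphill moves only)
#'   are run from the best configuration found.
#' @param moves_per_temp proposals per temperature step.
#' @param quench_sweeps zero-temperature finishing sweeps (default 50).
#' @param validate_every full-score revalidation interval, in sweeps.
#' @return List of class `dcs_anneal`: `cand` (assignments at the best
#'   configuration), `order`, `score`, `trajectory` (best score per sweep)
#'   and `seed`.
#' @export
anneal_pillars <- function(cand, gene_orders, seed, order = NULL,
                           t0 = 1.5, t_min = 0.01, cooling = 0.996,
                           moves_per_temp = NULL, quench_sweeps = 100L,
                           validate_every = 50L) {
  stopifnot(inherits(cand, "dcs_candidates"))
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (t0 <= t_min || t_min <= 0) stop("need t0 > t_min > 0", call. = FALSE)
  set.seed(as.integer(seed))
  m <- length(cand$anchors)
  all_cand <- unique(unlist(cand$candidates))
  codes <- gene_codes(gene_orders, cand$genome, all_cand)
  ord <- if (is.null(order)) seq_len(m) else as.integer(order)
  assign <- cand$assign
  cm <- matrix(codes_of(as.vector(assign), codes), ncol = 2L)
  used <- stats::setNames(rep(FALSE, length(all_cand)), all_cand)
  used[assign[!is.na(assign)]] <- TRUE
  pos_of <- integer(m); pos_of[ord] <- seq_len(m)

  full_score <- function() chain_score(cm[ord, 1L]) + chain_score(cm[ord, 2L])
  s <- full_score()
  best <- list(order = ord, assign = assign, score = s)
  if (is.null(moves_per_temp)) moves_per_temp <- max(40L, 2L * m)
  temp <- t0
  sweep <- 0L
  traj <- integer(0)

  one_sweep <- function(temp) {
    ## temp <= 0 means quench: only strictly improving moves are taken
    accept <- function(d) d > 0 ||
      (temp > 0 && (d == 0 || stats::runif(1) < exp(d / temp)))
    for (it in seq_len(moves_per_temp)) {
      mv <- sample.int(6L, 1L, prob = c(.35, .15, .05, .2, .1, .15))
      if (mv != 4L && mv != 5L && m < 2L) next
      if (mv == 6L) {
        ## reverse a segment and swap its slots: a DCS block read on the
        ## opposite strand; without this compound move such blocks are
        ## deep local optima
        ij <- sort(sample.int(m, 2L))
        rng <- ij[1L]:ij[2L]
        new_ord <- ord
        new_ord[rng] <- rev(new_ord[rng])
        pil <- ord[rng]
        new_cm <- cm
        new_cm[pil, ] <- cm[pil, 2:1, drop = FALSE]
        s_new <- chain_score(new_cm[new_ord, 1L]) + chain_score(new_cm[new_ord, 2L])
        if (accept(s_new - s)) {
          ord <<- new_ord; pos_of[new_ord] <<- seq_len(m)
          cm <<- new_cm
          assign[pil, ] <<- assign[pil, 2:1, drop = FALSE]
          s <<- s_new
        }
        if (s > best$score) best <<- list(order = ord, assign = assign, score = s)
        next
      }
      if (mv <= 3L) {
        new_ord <- ord
        if (mv == 1L) {                     # swap two pillars
          ij <- sample.int(m, 2L)
          new_ord[ij] <- new_ord[rev(ij)]
        } else if (mv == 2L) {              # relocate a segment
          len <- sample.int(min(8L, m - 1L), 1L)
          i <- sample.int(m - len + 1L, 1L)
          seg <- new_ord[i:(i + len - 1L)]
          rest <- new_ord[-(i:(i + len - 1L))]
          at <- sample.int(length(rest) + 1L, 1L)
          new_ord <- append(rest, seg, after = at - 1L)
        } else {                            # reverse a segment
          ij <- sort(sample.int(m, 2L))
          new_ord[ij[1L]:ij[2L]] <- rev(new_ord[ij[1L]:ij[2L]])
        }
        s_new <- chain_score(cm[new_ord, 1L]) + chain_score(cm[new_ord, 2L])
        if (accept(s_new - s)) {
          ord <<- new_ord; s <<- s_new
          pos_of[new_ord] <<- seq_len(m)
        }
      } else if (mv == 4L) {                # reassign one slot
        p <- sample.int(m, 1L)
        k <- sample.int(2L, 1L)
        cur <- assign[p, k]
        other <- assign[p, 3L - k]
        opts <- cand$candidates[[p]]
        opts <- opts[!used[opts]]
        opts <- setdiff(opts, other)
        choices <- c(opts, NA_character_)
        choices <- choices[is.na(choices) != is.na(cur) |
                             (!is.na(choices) & !is.na(cur) & choices != cur)]
        if (!length(choices)) next
        new_gene <- sample(choices, 1L)
        pos <- pos_of[p]
        v <- cm[ord, k]
        old_terms <- local_chain_terms(v, pos)
        v[pos] <- codes_of(new_gene, codes)
        new_terms <- local_chain_terms(v, pos)
        d <- new_terms - old_terms
        if (accept(d)) {
          if (!is.na(cur)) used[cur] <<- FALSE
          if (!is.na(new_gene)) used[new_gene] <<- TRUE
          assign[p, k] <<- new_gene
          cm[p, k] <<- v[pos]
          s <<- s + d
        }
      } else {                              # swap a pillar's two slots
        p <- sample.int(m, 1L)
        pos <- pos_of[p]
        d <- 0L
        v1 <- cm[ord, 1L]; v2 <- cm[ord, 2L]
        d <- d - local_chain_terms(v1, pos) - local_chain_terms(v2, pos)
        tmp <- v1[pos]; v1[pos] <- v2[pos]; v2[pos] <- tmp
        d <- d + local_chain_terms(v1, pos) + local_chain_terms(v2, pos)
        if (accept(d)) {
          assign[p, ] <<- assign[p, 2:1]
          cm[p, ] <<- cm[p, 2:1]
          s <<- s + d
        }
      }
      if (s > best$score) best <<- list(order = ord, assign = assign, score = s)
    }
    invisible(NULL)
  }

  while (temp > t_min) {
    sweep <- sweep + 1L
    one_sweep(temp)
    if (sweep %% validate_every == 0L && s != full_score())
      stop("internal error: incremental synteny score drifted from full recomputation")
    traj <- c(traj, best$score)
    temp <- temp * cooling
  }
  ## quench: restart from the best configuration and hill-climb
  ord <- best$order; assign <- best$assign; s <- best$score
  cm <- matrix(codes_of(as.vector(assign), codes), ncol = 2L)
  pos_of[ord] <- seq_len(m)
  used[] <- FALSE
  used[assign[!is.na(assign)]] <- TRUE
  for (q in seq_len(quench_sweeps)) one_sweep(0)
  traj <- c(traj, best$score)
  if (s != full_score())
    stop("internal error: incremental synteny score drifted from full recomputation")
  out_cand <- cand
  out_cand$assign <- best$assign
  structure(list(cand = out_cand, order = best$order, score = best$score,
                 trajectory = traj, seed = as.integer(seed)),
            class = "dcs_anneal")
}

#' Merge per-genome pillar inferences into a multi-genome pillar set
#'
#' Implements the cross-genome merge: within each genome, an assigned gene
#' is kept only if at least one of its genomic neighbors is also assigned
#' somewhere in that genome's pillar set (synteny support); a pillar
#' survives the merge only if every genome still contributes at least one
#' gene. Pillars are indexed by their shared outgroup anchors and returned
#' in outgroup order.
#'
#' @param anneals named list (one per genome) of [anneal_pillars()] results
#'   or [dcs_candidates()] objects with assignments; all must share the
#'   same anchor vector.
#' @param gene_orders annotation data frame.
#' @return A [pillar_set()] with gene ids.
#' @export
merge_pillars <- function(anneals, gene_orders) {
  get_cand <- function(a) if (inherits(a, "dcs_anneal")) a$cand else a
  cands <- lapply(anneals, get_cand)
  anchors <- cands[[1L]]$anchors
  for (cd in cands)
    if (!identical(cd$anchors, anchors))
      stop("all per-genome pillar sets must share the same anchors", call. = FALSE)
  genomes <- vapply(cands, function(cd) cd$genome, "")
  m <- length(anchors); n <- length(cands)
  p1 <- p2 <- matrix(NA_character_, m, n, dimnames = list(NULL, genomes))
  for (g in seq_len(n)) {
    cd <- cands[[g]]
    codes <- gene_codes(gene_orders, cd$genome, unique(unlist(cd$candidates)))
    asg <- cd$assign
    acode <- matrix(codes_of(as.vector(asg), codes), ncol = 2L)
    in_set <- stats::na.omit(as.vector(acode))
    supported <- function(code) !is.na(code) &
      ((code + 1) %in% in_set | (code - 1) %in% in_set)
    keep1 <- supported(acode[, 1L]); keep2 <- supported(acode[, 2L])
    p1[keep1, g] <- asg[keep1, 1L]
    p2[keep2, g] <- asg[keep2, 2L]
  }
  occupied <- (!is.na(p1)) | (!is.na(p2))
  keep <- rowSums(occupied) == n
  if (!any(keep)) stop("no pillar has a gene from every genome after merging", call. = FALSE)
  p1 <- p1[keep, , drop = FALSE]; p2 <- p2[keep, , drop = FALSE]
  obs <- matrix(OBS_DUPLICATED, sum(keep), n)
  obs[!is.na(p1) & is.na(p2)] <- OBS_SINGLE_P1
  obs[is.na(p1) & !is.na(p2)] <- OBS_SINGLE_P2
  colnames(obs) <- genomes
  pillar_set(obs, genomes = genomes, anchors = anchors[keep],
             genes = list(p1 = p1, p2 = p2))
}

#' Optimise the global ancestral pillar order
#'
#' With all slot assignments held fixed, anneals the order of the merged
#' multi-genome pillars so as to maximise the total number of neighbor
#' relationships across all genomes and slots. Supports several seeded
#' replicates, returned ranked by score.
#'
#' @param pillars a merged [pillar_set()] with gene ids.
#' @param gene_orders annotation data frame.
#' @param seed integer seed; replicate `r` uses `seed + r - 1`.
#' @param replicates number of annealing replicates.
#' @param order initial order (default `1..m`, the outgroup order).
#' @inheritParams anneal_pillars
#' @return List of class `order_search`: `best` (list with `order`,
#'   `score`, `seed`), `replicates` (all runs, ranked), `initial_score`.
#' @export
optimize_global_order <- function(pillars, gene_orders, seed, replicates = 1L,
                                  order = NULL, t0 = 1.5, t_min = 0.01,
                                  cooling = 0.996, moves_per_temp = NULL,
                                  quench_sweeps = 100L) {
  stopifnot(inherits(pillars, "pillar_set"))
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  cms <- code_matrices(pillars, gene_orders)
  m <- n_pillars(pillars)
  score_of <- function(o) {
    s <- 0L
    for (cm in cms) s <- s + chain_score(cm[o, 1L]) + chain_score(cm[o, 2L])
    s
  }
  init <- if (is.null(order)) seq_len(m) else as.integer(order)
  init_score <- score_of(init)
  if (is.null(moves_per_temp)) moves_per_temp <- max(40L, 2L * m)
  propose <- function(ord) {
    mv <- sample.int(3L, 1L, prob = c(4, 2, 1))
    new_ord <- ord
    if (mv == 1L) {
      ij <- sample.int(m, 2L)
      new_ord[ij] <- new_ord[rev(ij)]
    } else if (mv == 2L) {
      len <- sample.int(min(8L, m - 1L), 1L)
      i <- sample.int(m - len + 1L, 1L)
      seg <- new_ord[i:(i + len - 1L)]
      rest <- new_ord[-(i:(i + len - 1L))]
      at <- sample.int(length(rest) + 1L, 1L)
      new_ord <- append(rest, seg, after = at - 1L)
    } else {
      ij <- sort(sample.int(m, 2L))
      new_ord[ij[1L]:ij[2L]] <- rev(new_ord[ij[1L]:ij[2L]])
    }
    new_ord
  }
  runs <- lapply(seq_len(replicates), function(r) {
    set.seed(as.integer(seed) + r - 1L)
    ord <- init
    s <- init_score
    best <- list(order = ord, score = s, seed = as.integer(seed) + r - 1L)
    temp <- t0
    while (temp > t_min) {
      if (m < 2L) break
      for (it in seq_len(moves_per_temp)) {
        new_ord <- propose(ord)
        s_new <- score_of(new_ord)
        if (s_new >= s || stats::runif(1) < exp((s_new - s) / temp)) {
          ord <- new_ord; s <- s_new
          if (s > best$score) best <- list(order = ord, score = s, seed = best$seed)
        }
      }
      temp <- temp * cooling
    }
    ## quench from the best order: strictly improving moves only
    ord <- best$order; s <- best$score
    if (m >= 2L) for (q in seq_len(quench_sweeps)) {
      for (it in seq_len(moves_per_temp)) {
        new_ord <- propose(ord)
        s_new <- score_of(new_ord)
        if (s_new > s) {
          ord <- new_ord; s <- s_new
          best <- list(order = ord, score = s, seed = best$seed)
        }
      }
    }
    best
  })
  runs <- runs[order(-vapply(runs, function(r) r$score, 0L))]
  structure(list(best = runs[[1L]], replicates = runs,
                 initial_score = init_score),
            class = "order_search")
}

#' Reorder a pillar set
#'
#' Applies a pillar permutation. Junction double-break flags are cleared
#' (they are order-dependent); recompute them with [detect_breaks()].
#'
#' @param pillars a [pillar_set()].
#' @param order permutation of `1..m`.
#' @return A [pillar_set()].
#' @export
reorder_pillars <- function(pillars, order) {
  order <- as.integer(order)
  stopifnot(identical(sort(order), seq_len(n_pillars(pillars))))
  pillar_set(pillars$obs[order, , drop = FALSE], genomes = pillars$genomes,
             anchors = pillars$anchors[order],
             genes = if (!is.null(pillars$genes))
               list(p1 = pillars$genes$p1[order, , drop = FALSE],
                    p2 = pillars$genes$p2[order, , drop = FALSE]),
             truth = pillars$truth)
}

#' High-synteny subset of a pillar set
#'
#' Retains only pillars with full syntenic support in at least one
#' direction: for every genome, there must be a direction (towards the
#' previous or the next pillars) in which every occupied slot's gene is a
#' genomic neighbor of the next non-empty same-slot gene. Pillars failing
#' this in any genome are dropped; the survivors form a new pillar set in
#' the same relative order.
#'
#' @inheritParams detect_breaks
#' @return A [pillar_set()].
#' @export
high_synteny_subset <- function(x, gene_orders, order = NULL) {
  stopifnot(inherits(x, "pillar_set"))
  cms <- code_matrices(x, gene_orders)
  m <- n_pillars(x); n <- length(cms)
  if (is.null(order)) order <- seq_len(m)
  linked <- array(NA, c(m, n, 2L, 2L))  # [pillar, genome, slot, direction]
  for (g in seq_len(n)) for (k in 1:2) {
    v <- cms[[g]][order, k]
    filled <- which(!is.na(v))
    if (length(filled) > 1L) {
      ok <- abs(diff(v[filled])) == 1
      linked[order[filled[-length(filled)]], g, k, 2L] <- ok  # toward successor
      linked[order[filled[-1L]], g, k, 1L] <- ok              # toward predecessor
    }
  }
  occ <- array(FALSE, c(m, n, 2L))
  occ[, , 1L] <- x$obs != OBS_SINGLE_P2
  occ[, , 2L] <- x$obs != OBS_SINGLE_P1
  keep <- logical(m)
  for (i in seq_len(m)) {
    ok_g <- logical(n)
    for (g in seq_len(n)) {
      dir_ok <- function(d) {
        ks <- which(occ[i, g, ])
        all(vapply(ks, function(k) isTRUE(linked[i, g, k, d]), TRUE))
      }
      ok_g[g] <- dir_ok(1L) || dir_ok(2L)
    }
    keep[i] <- all(ok_g)
  }
  if (!any(keep)) {
    ## empty result: return a zero-pillar marker the caller can test
    return(structure(list(obs = x$obs[0, , drop = FALSE], genomes = x$genomes,
                          anchors = character(0),
                          double_break = matrix(FALSE, 0, n_genomes(x)),
                          genes = NULL, truth = NULL),
                     class = "pillar_set"))
  }
  idx <- which(keep)
  pillar_set(x$obs[idx, , drop = FALSE], genomes = x$genomes,
             anchors = x$anchors[idx],
             genes = if (!is.null(x$genes))
               list(p1 = x$genes$p1[idx, , drop = FALSE],
                    p2 = x$genes$p2[idx, , drop = FALSE]))
}

#' Filter candidate homolog pairs
#'
#' Applies the homology acceptance rules used to seed pillar candidates.
#' In `"seed"` mode a pair is accepted when the two proteins share at least
#' `min_seven_mers` exact 7-residue matches, the shorter sequence is at
#' least `min_len_ratio` of the longer, and overall amino-acid identity is
#' at least `min_identity`. In `"blast"` mode the 7-mer requirement is
#' replaced by an E-value cutoff. When a `ka` column is present,
#' nonsynonymous divergence above `max_ka` is rejected as well (guarding
#' against homology surviving from older shared polyploidies); `max_ka`
#' may be a single value or a named vector keyed by the `genome` column.
#'
#' @param pairs data frame with columns `identity`, `len_ratio` and, per
#'   mode, `seven_mer_count` or `evalue`; optionally `ka` and `genome`.
#' @param mode `"seed"` or `"blast"`.
#' @param min_identity minimum amino-acid identity (default 0.70).
#' @param min_len_ratio minimum shorter/longer length ratio (default 0.8).
#' @param min_seven_mers minimum shared exact 7-mers, seed mode (default 2).
#' @param max_evalue maximum E-value, blast mode (default 1e-8).
#' @param max_ka maximum Ka (default 0.1); ignored when `pairs` has no `ka`
#'   column.
#' @return The accepted subset of `pairs`.
#' @export
filter_homolog_pairs <- function(pairs, mode = c("seed", "blast"),
                                 min_identity = 0.70, min_len_ratio = 0.8,
                                 min_seven_mers = 2L, max_evalue = 1e-8,
                                 max_ka = 0.1) {
  mode <- match.arg(mode)
  need <- c("identity", "len_ratio",
            if (mode == "seed") "seven_mer_count" else "evalue")
  miss <- setdiff(need, names(pairs))
  if (length(miss))
    stop("`pairs` lacks required column(s) for ", mode, " mode: ",
         paste(miss, collapse = ", "), call. = FALSE)
  ok <- pairs$identity >= min_identity & pairs$len_ratio >= min_len_ratio
  ok <- ok & if (mode == "seed") pairs$seven_mer_count >= min_seven_mers
             else pairs$evalue <= max_evalue
  if ("ka" %in% names(pairs) && !is.null(max_ka)) {
    cutoff <- if (length(max_ka) > 1L) {
      if (!"genome" %in% names(pairs))
        stop("per-genome `max_ka` needs a `genome` column", call. = FALSE)
      unname(max_ka[pairs$genome])
    } else max_ka
    ok <- ok & (is.na(pairs$ka) | pairs$ka <= cutoff)
  }
  pairs[which(ok), , drop = FALSE]
}

#' Shared exact 7-mer count between two protein sequences
#'
#' Counts the distinct 7-residue substrings occurring in both sequences;
#' together with length ratio and identity this seeds the fast homology
#' filter.
#'
#' @param a,b character strings (amino-acid sequences).
#' @param k word length (default 7).
#' @return Integer count of distinct shared k-mers.
#' @export
count_shared_kmers <- function(a, b, k = 7L) {
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  }
  length(intersect(kmers(a), kmers(b)))
}
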