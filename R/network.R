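#' Count subgenome-crossing interactions
#'
#' Number of edges whose endpoints carry different parental-subgenome
#' labels. Every endpoint must be labeled.
#'
#' @param edges data frame (or two-column matrix) of gene id pairs.
#' @param labels named vector (values 1/2) of subgenome labels.
#' @return Integer count.
#' @export
crossing_count <- function(edges, labels) {
  edges <- as.matrix(edges[, 1:2])
  la <- labels[edges[, 1L]]; lb <- labels[edges[, 2L]]
  if (anyNA(la) || anyNA(lb)) {
    bad <- unique(c(edges[, 1L][is.na(la)], edges[, 2L][is.na(lb)]))
    stop("unlabeled edge endpoint(s): ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  }
  sum(la != lb)
}

#' Permutation test for a paucity of cross-subgenome interactions
#'
#' Tests whether interactions between products of genes from alternative
#' subgenomes are rarer than expected by chance, by comparing the observed
#' crossing count to its distribution under random reassignment of the
#' subgenome labels (the label multiset is preserved). The one-sided
#' p-value uses the add-one estimator `(1 + #{null <= observed}) /
#' (1 + n_rand)`.
#'
#' With `unit = "pillar"`, labels are instead flipped jointly for all genes
#' of the same group (e.g. one pillar), preserving within-group linkage;
#' supply `groups` in that case.
#'
#' @inheritParams crossing_count
#' @param n_rand number of label randomizations (default 1000).
#' @param seed integer seed.
#' @param unit permutation unit: `"gene"` (default; labels shuffled across
#'   genes) or `"pillar"` (each group's labels flipped together).
#' @param groups named vector mapping gene id to group, for
#'   `unit = "pillar"`.
#' @return List with `observed`, `null_mean`, `p_value`, `n_rand`.
#' @export
randomization_test <- function(edges, labels, n_rand = 1000L, seed = 1L,
                               unit = c("gene", "pillar"), groups = NULL) {
  unit <- match.arg(unit)
  if (n_rand < 1L) stop("`n_rand` must be >= 1", call. = FALSE)
  if (nrow(edges) < 1L) stop("need at least one edge", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("degenerate label multiset: both subgenomes must be present; ",
         "p-value undefined", call. = FALSE)
  obs <- crossing_count(edges, labels)
  set.seed(as.integer(seed))
  nulls <- integer(n_rand)
  if (unit == "gene") {
    for (r in seq_len(n_rand)) {
      perm <- stats::setNames(sample(labels), names(labels))
      nulls[r] <- crossing_count(edges, perm)
    }
  } else {
    if (is.null(groups)) stop("`groups` required for pillar-level permutation", call. = FALSE)
    grp <- groups[names(labels)]
    ug <- unique(grp)
    for (r in seq_len(n_rand)) {
      flip <- stats::setNames(sample(c(TRUE, FALSE), length(ug), replace = TRUE), ug)
      perm <- ifelse(flip[grp], 3L - labels, labels)
      names(perm) <- names(labels)
      nulls[r] <- crossing_count(edges, perm)
    }
  }
  list(observed = obs, null_mean = mean(nulls),
       p_value = (1 + sum(nulls <= obs)) / (1 + n_rand), n_rand = n_rand)
}

#' Crossing-interaction test across assignment-confidence thresholds
#'
#' Repeats the randomization test over a range of confidence cutoffs on the
#' subgenome assignment: at each threshold only single-copy genes whose
#' assignment confidence reaches the threshold are retained, the
#' permutation test is run on the induced edge set, and the frequency of
#' crossing interactions relative to same-subgenome interactions is
#' reported. If genuine depletion is diluted by mislabeled genes, the
#' crossing ratio should fall as the threshold rises.
#'
#' @inheritParams randomization_test
#' @param confidence named numeric vector in `[0.5, 1]`: per-gene
#'   assignment confidence.
#' @param thresholds numeric vector of cutoffs in `(0.5, 1]`.
#' @return Data frame with one row per threshold: `threshold`, `n_genes`,
#'   `n_edges`, `observed`, `null_mean`, `p_value`, `crossing_ratio`.
#'   Thresholds leaving fewer than two labeled genes or no edges give `NA`
#'   rows.
#' @export
confidence_sweep <- function(edges, labels, confidence,
                             thresholds = seq(0.5, 0.95, by = 0.05),
                             n_rand = 1000L, seed = 1L) {
  out <- lapply(thresholds, function(th) {
    keep <- names(confidence)[confidence >= th]
    lab <- labels[intersect(names(labels), keep)]
    e <- edges[edges[[1L]] %in% names(lab) & edges[[2L]] %in% names(lab), , drop = FALSE]
    empty <- data.frame(threshold = th, n_genes = length(lab), n_edges = nrow(e),
                        observed = NA_integer_, null_mean = NA_real_,
                        p_value = NA_real_, crossing_ratio = NA_real_)
    if (length(lab) < 2L || nrow(e) < 1L || length(unique(lab)) < 2L) return(empty)
    rt <- randomization_test(e, lab, n_rand = n_rand, seed = seed)
    same <- nrow(e) - rt$observed
    empty$observed <- rt$observed
    empty$null_mean <- rt$null_mean
    empty$p_value <- rt$p_value
    empty$crossing_ratio <- if (same > 0) rt$observed / same else NA_real_
    empty
  })
  do.call(rbind, out)
}

#' Subgenome labels of single-copy genes from a posterior decoding
#'
#' Extracts, from a pillar set and its posterior, every single-copy gene
#' together with its inferred parental subgenome (1 or 2) and the
#' confidence of that call.
#'
#' @param pillars a [pillar_set()] with gene ids.
#' @param posterior matching [posterior_assignments()] result.
#' @return Data frame: `gene`, `genome`, `pillar`, `subgenome`,
#'   `confidence`.
#' @export
single_copy_labels <- function(pillars, posterior) {
  stopifnot(inherits(pillars, "pillar_set"), !is.null(pillars$genes))
  m <- n_pillars(pillars); n <- n_genomes(pillars)
  rows <- list()
  for (g in seq_len(n)) {
    single1 <- pillars$obs[, g] == OBS_SINGLE_P1
    single2 <- pillars$obs[, g] == OBS_SINGLE_P2
    ## slot p1 single: gene's subgenome is 1 with prob marginal1
    p1m <- posterior$marginal1[, g]
    idx1 <- which(single1); idx2 <- which(single2)
    if (length(idx1))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = pillars$genes$p1[idx1, g], genome = pillars$genomes[g],
        pillar = idx1,
        subgenome = ifelse(p1m[idx1] >= 0.5, 1L, 2L),
        confidence = pmax(p1m[idx1], 1 - p1m[idx1]))
    if (length(idx2))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = pillars$genes$p2[idx2, g], genome = pillars$genomes[g],
        pillar = idx2,
        subgenome = ifelse(p1m[idx2] >= 0.5, 2L, 1L),
        confidence = pmax(p1m[idx2], 1 - p1m[idx2]))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
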