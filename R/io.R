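#' Read per-genome gene orders
#'
#' Reads a TSV of gene-order annotations with header columns `genome`,
#' `chromosome`, `position`, `gene_id`. Positions need not be dense: only
#' their rank within a chromosome matters. Two genes are genomic neighbors
#' when they are adjacent, within the current analysis set, on the same
#' chromosome.
#'
#' @param path path to a tab-separated file.
#' @return Data frame with the four columns, checked for duplicate gene ids
#'   within a genome.
#' @export
read_gene_orders <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome", "chromosome", "position", "gene_id")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("gene-order file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(d$position)) stop("`position` must be numeric", call. = FALSE)
  dup <- d[duplicated(d[c("genome", "gene_id")]), ]
  if (nrow(dup))
    stop("duplicate gene_id within a genome: ",
         paste(utils::head(paste(dup$genome, dup$gene_id, sep = ":"), 5L),
               collapse = ", "), call. = FALSE)
  d[need]
}

#' Write / read a pillar set as TSV
#'
#' One row per pillar: `anchor`, 0-based `order_index`, then per genome the
#' slot gene ids `<genome>.p1` / `<genome>.p2` (`-` for an empty slot) and
#' the junction double-break flag `<genome>.dbreak` (flag on row `i` refers
#' to the junction between pillars `i` and `i + 1`; the last row is always
#' 0). Round-trips losslessly when the pillar set carries gene ids.
#'
#' @param pillars a [pillar_set()] with gene ids.
#' @param path output path.
#' @return `write_pillars` returns `path` invisibly; `read_pillars` a
#'   [pillar_set()].
#' @export
write_pillars <- function(pillars, path) {
  stopifnot(inherits(pillars, "pillar_set"))
  if (is.null(pillars$genes))
    stop("pillar set carries no gene ids; simulate or build pillars with genes",
         call. = FALSE)
  m <- n_pillars(pillars); n <- n_genomes(pillars)
  out <- data.frame(anchor = pillars$anchors, order_index = seq_len(m) - 1L)
  for (g in seq_len(n)) {
    gn <- pillars$genomes[g]
    p1 <- pillars$genes$p1[, g]; p2 <- pillars$genes$p2[, g]
    db <- c(pillars$double_break[, g], FALSE)[seq_len(m)]
    out[[paste0(gn, ".p1")]] <- ifelse(is.na(p1), "-", p1)
    out[[paste0(gn, ".p2")]] <- ifelse(is.na(p2), "-", p2)
    out[[paste0(gn, ".dbreak")]] <- as.integer(db)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pillars
#' @export
read_pillars <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("anchor", "order_index") %in% names(d)))
    stop("pillar file lacks `anchor`/`order_index` columns", call. = FALSE)
  p1_cols <- grep("\\.p1$", names(d), value = TRUE)
  genomes <- sub("\\.p1$", "", p1_cols)
  if (!length(genomes)) stop("pillar file has no `<genome>.p1` columns", call. = FALSE)
  for (gn in genomes) {
    want <- paste0(gn, c(".p2", ".dbreak"))
    miss <- setdiff(want, names(d))
    if (length(miss))
      stop("pillar file lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  m <- nrow(d); n <- length(genomes)
  p1 <- p2 <- matrix(NA_character_, m, n, dimnames = list(NULL, genomes))
  db <- matrix(FALSE, max(m - 1L, 0L), n)
  for (g in seq_len(n)) {
    gn <- genomes[g]
    a <- d[[paste0(gn, ".p1")]]; b <- d[[paste0(gn, ".p2")]]
    p1[, g] <- ifelse(a == "-", NA_character_, a)
    p2[, g] <- ifelse(b == "-", NA_character_, b)
    if (m > 1L) db[, g] <- as.logical(d[[paste0(gn, ".dbreak")]][-m])
  }
  occ1 <- !is.na(p1); occ2 <- !is.na(p2)
  bad <- which(!occ1 & !occ2)
  if (length(bad))
    stop("pillar row(s) with no gene for a genome (line ",
         paste(utils::head(bad %% m, 5L) + 1L, collapse = ", "), ")", call. = FALSE)
  obs <- matrix(OBS_DUPLICATED, m, n)
  obs[occ1 & !occ2] <- OBS_SINGLE_P1
  obs[!occ1 & occ2] <- OBS_SINGLE_P2
  colnames(obs) <- genomes
  pillar_set(obs, genomes = genomes, anchors = as.character(d$anchor),
             double_break = db, genes = list(p1 = p1, p2 = p2))
}

#' Write / read posterior assignment tables
#'
#' One row per pillar: `anchor`, `order_index`, the posterior probability
#' of every assignment vector (columns `v<bits>`, where the bit string
#' gives each genome's subgenome, e.g. `v112` = genomes 1 and 2 on
#' subgenome 1, genome 3 on subgenome 2), and the per-genome subgenome-1
#' marginals (`<genome>.P1`). Probabilities are serialized with 15
#' significant digits.
#'
#' @param posterior a [posterior_assignments()] result.
#' @param pillars the matching [pillar_set()].
#' @param path output path.
#' @return `write_posteriors` returns `path` invisibly; `read_posteriors` a
#'   list with `prob`, `marginal1`, `anchors`.
#' @export
write_posteriors <- function(posterior, pillars, path) {
  stopifnot(inherits(posterior, "wgd_posterior"))
  m <- nrow(posterior$prob)
  vlab <- apply(posterior$vectors, 1L, paste, collapse = "")
  out <- data.frame(anchor = pillars$anchors, order_index = seq_len(m) - 1L)
  for (j in seq_len(ncol(posterior$prob)))
    out[[paste0("v", vlab[j])]] <- format(posterior$prob[, j], digits = 15L,
                                          scientific = TRUE, trim = TRUE)
  for (g in seq_along(posterior$genomes))
    out[[paste0(posterior$genomes[g], ".P1")]] <-
      format(posterior$marginal1[, g], digits = 15L, scientific = TRUE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_posteriors
#' @export
read_posteriors <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  vcols <- grep("^v[12]+$", names(d), value = TRUE)
  mcols <- grep("\\.P1$", names(d), value = TRUE)
  prob <- as.matrix(d[vcols])
  marg <- as.matrix(d[mcols])
  colnames(marg) <- sub("\\.P1$", "", mcols)
  list(prob = prob, marginal1 = marg, anchors = d$anchor)
}

#' Write a fit report as JSON
#'
#' @param fit a `wgd_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "wgd_fit"))
  rep <- list(family = fit$family, logLik = fit$logLik, df = fit$df,
              gamma = fit$gamma, epsilon = fit$epsilon,
              epsilon_early = fit$epsilon_early, theta = fit$theta,
              branch_lengths = fit$branch_lengths,
              newick = ape::write.tree(fit$model$tree),
              convergence = fit$convergence, seed = fit$seed)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
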