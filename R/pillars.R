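## Observation codes, one per genome per pillar:
##   1 = duplicated        (both homoeologous slots occupied)
##   2 = single_in_p1      (only the slot-1 track retains a gene)
##   3 = single_in_p2      (only the slot-2 track retains a gene)
OBS_DUPLICATED <- 1L
OBS_SINGLE_P1  <- 2L
OBS_SINGLE_P2  <- 3L
OBS_LEVELS <- c("duplicated", "single_in_p1", "single_in_p2")

#' Create a set of ancestral pillars
#'
#' A pillar is one ancestral locus: an outgroup anchor gene plus, for each
#' polyploid genome, the genes filling its two homoeologous slots (`p1`,
#' `p2`). Each genome contributes at least one gene per pillar, so its
#' observation is one of `"duplicated"`, `"single_in_p1"` or
#' `"single_in_p2"`. Pillars are ordered along the inferred ancestral
#' chromosome; the junction between pillars `i` and `i + 1` may carry a
#' per-genome double-synteny-break flag, at which the subgenome assignment of
#' that genome decorrelates completely.
#'
#' @param obs an `m x n` matrix of observations, either integer codes (1 =
#'   duplicated, 2 = single in p1, 3 = single in p2) or the corresponding
#'   character labels; one column per genome.
#' @param genomes character vector of genome names; defaults to the column
#'   names of `obs`.
#' @param anchors character vector of outgroup anchor gene ids (defaults to
#'   `"anc<i>"`).
#' @param double_break logical `(m - 1) x n` matrix; entry `[i, g]` flags a
#'   double synteny break in genome `g` between pillars `i` and `i + 1`.
#' @param genes optional list with character matrices `p1` and `p2` (`m x n`)
#'   of the gene ids occupying each slot (`NA` for empty slots).
#' @param truth optional list of simulation truth (kept as-is).
#' @return An object of class `pillar_set`.
#' @examples
#' ps <- pillar_set(matrix(c(1, 2, 1, 3), 2, 2,
#'                         dimnames = list(NULL, c("gA", "gB"))))
#' ps
#' @export
pillar_set <- function(obs, genomes = colnames(obs), anchors = NULL,
                       double_break = NULL, genes = NULL, truth = NULL) {
  if (is.character(obs)) {
    oo <- match(obs, OBS_LEVELS)
    if (anyNA(oo)) stop("unknown observation label in `obs`", call. = FALSE)
    obs <- matrix(as.integer(oo), nrow(obs), ncol(obs), dimnames = dimnames(obs))
  }
  obs <- as.matrix(obs)
  storage.mode(obs) <- "integer"
  m <- nrow(obs); n <- ncol(obs)
  if (m < 1L || n < 1L) stop("`obs` must have at least one pillar and one genome", call. = FALSE)
  if (!all(obs %in% 1:3)) stop("observation codes must be in 1:3", call. = FALSE)
  if (is.null(genomes)) genomes <- paste0("g", seq_len(n))
  if (length(genomes) != n) stop("`genomes` must name every column of `obs`", call. = FALSE)
  colnames(obs) <- genomes
  if (is.null(anchors)) anchors <- sprintf("anc%04d", seq_len(m))
  if (length(anchors) != m) stop("need one anchor per pillar", call. = FALSE)
  if (is.null(double_break)) {
    double_break <- matrix(FALSE, max(m - 1L, 0L), n)
  } else {
    double_break <- as.matrix(double_break)
    if (nrow(double_break) != m - 1L || ncol(double_break) != n)
      stop("`double_break` must be (m - 1) x n", call. = FALSE)
    storage.mode(double_break) <- "logical"
  }
  colnames(double_break) <- genomes
  if (!is.null(genes)) {
    stopifnot(is.list(genes), all(c("p1", "p2") %in% names(genes)))
    occ1 <- !is.na(genes$p1); occ2 <- !is.na(genes$p2)
    implied <- matrix(OBS_DUPLICATED, m, n)
    implied[occ1 & !occ2] <- OBS_SINGLE_P1
    implied[!occ1 & occ2] <- OBS_SINGLE_P2
    if (any(!occ1 & !occ2))
      stop("every genome must occupy at least one slot in every pillar", call. = FALSE)
    if (any(implied != obs))
      stop("`genes` slot occupancy contradicts `obs`", call. = FALSE)
  }
  structure(list(obs = obs, genomes = as.character(genomes),
                 anchors = as.character(anchors),
                 double_break = double_break, genes = genes, truth = truth),
            class = "pillar_set")
}

#' @export
print.pillar_set <- function(x, ...) {
  m <- n_pillars(x); n <- n_genomes(x)
  cat(sprintf("pillar_set: %d pillars x %d genomes (%s)\n",
              m, n, paste(x$genomes, collapse = ", ")))
  tab <- table(factor(OBS_LEVELS[x$obs], levels = OBS_LEVELS))
  cat("  observations:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  double-break flags: %d of %d junction-genome pairs\n",
              sum(x$double_break), length(x$double_break)))
  invisible(x)
}

#' @rdname pillar_set
#' @param x a `pillar_set`.
#' @export
n_pillars <- function(x) nrow(x$obs)

#' @rdname pillar_set
#' @export
n_genomes <- function(x) ncol(x$obs)

#' Extract a contiguous run of pillars
#'
#' Subsets a `pillar_set` to the contiguous pillar range `i`, keeping the
#' junction (double-break) flags interior to the range. Only contiguous,
#' increasing ranges are meaningful because pillar order carries the
#' information.
#'
#' @param x a `pillar_set`.
#' @param i integer vector of consecutive pillar indices.
#' @param ... ignored.
#' @return A `pillar_set` over the selected pillars.
#' @export
`[.pillar_set` <- function(x, i, ...) {
  i <- as.integer(i)
  if (length(i) < 1L || any(diff(i) != 1L))
    stop("pillar subsets must be contiguous increasing ranges", call. = FALSE)
  keep_j <- if (length(i) > 1L) i[-length(i)] else integer(0)
  pillar_set(x$obs[i, , drop = FALSE], genomes = x$genomes,
             anchors = x$anchors[i],
             double_break = x$double_break[keep_j, , drop = FALSE],
             genes = if (!is.null(x$genes))
               list(p1 = x$genes$p1[i, , drop = FALSE],
                    p2 = x$genes$p2[i, , drop = FALSE]),
             truth = NULL)
}
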