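## Model families, ordered by nesting:
##   n   - balanced loss only (gamma = 0, epsilon = 1)
##   f   - duplicate fixation (gamma free, epsilon = 1)
##   b   - biased fractionation (gamma = 0, epsilon free)
##   bf  - both free
##   btf - bf with a separate epsilon on the "early" (root-incident) branches
WGD_FAMILIES <- c("n", "f", "b", "bf", "btf")

family_spec <- function(family) {
  family <- match.arg(family, WGD_FAMILIES)
  list(family = family,
       gamma_free = family %in% c("f", "bf", "btf"),
       eps_free = family %in% c("b", "bf", "btf"),
       eps_early_free = family == "btf")
}

#' Maximum-likelihood fit of a duplicate-loss model family
#'
#' Fits one of the nested model families to an ordered pillar set by
#' maximising [sequence_loglik()] over the per-branch lengths, the global
#' switching probability `theta`, and whichever of `gamma` (fixation) and
#' `epsilon` (fractionation bias) the family leaves free. Family `"btf"`
#' additionally frees a separate `epsilon_early` on a designated branch
#' class (default: the branches incident to the root, i.e. the shared
#' post-WGD interval). Optimisation uses bound-constrained quasi-Newton
#' (`L-BFGS-B`) followed by a polishing restart; non-convergence is flagged
#' in the result rather than raised.
#'
#' @param pillars a [pillar_set()].
#' @param tree rooted `phylo` topology over the pillar genomes. Branch
#'   lengths, if present, seed the optimiser; otherwise a default start is
#'   used.
#' @param family one of `"n"`, `"f"`, `"b"`, `"bf"`, `"btf"`.
#' @param early_edges early branch class for `"btf"` (postorder edge
#'   indices; default root-incident edges).
#' @param theta fixed value for `theta`, or `NULL` (default) to estimate it.
#' @param restarts number of additional jittered starting points.
#' @param seed integer seed controlling the jittered restarts.
#' @param init optional named list of starting values (`gamma`, `epsilon`,
#'   `epsilon_early`, `theta`) overriding the defaults; useful to warm-start
#'   a fuller family from a nested fit so nested likelihood ratios cannot go
#'   negative.
#' @param control optional list: `maxit` (default 200), `b_max` (branch
#'   length upper bound, default 20), `gamma_max` (default 20).
#' @return An object of class `wgd_fit` with elements `family`, `logLik`,
#'   `gamma`, `epsilon`, `epsilon_early`, `theta`, `branch_lengths`,
#'   `model` (a [loss_model()] at the MLE), `df` (number of free
#'   parameters), `convergence` (0 = converged) and `seed`.
#' @export
fit_model <- function(pillars, tree, family = "bf", early_edges = NULL,
                      theta = NULL, restarts = 0L, seed = 1L,
                      init = list(), control = list()) {
  spec <- family_spec(family)
  stopifnot(inherits(pillars, "pillar_set"))
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object", call. = FALSE)
  ctl <- utils::modifyList(list(maxit = 200L, b_max = 20, gamma_max = 20), control)
  tree <- stats::reorder(tree, "postorder")
  E <- nrow(tree$edge)
  if (spec$eps_early_free && is.null(early_edges)) early_edges <- root_edges(tree)

  theta_free <- is.null(theta)
  ## parameter packing: E branch lengths, then [gamma], [epsilon],
  ## [epsilon_early], [theta]
  par_names <- c(paste0("b", seq_len(E)),
                 if (spec$gamma_free) "gamma",
                 if (spec$eps_free) "epsilon",
                 if (spec$eps_early_free) "epsilon_early",
                 if (theta_free) "theta")
  lower <- c(rep(1e-6, E),
             if (spec$gamma_free) 0,
             if (spec$eps_free) 0,
             if (spec$eps_early_free) 0,
             if (theta_free) 1e-6)
  upper <- c(rep(ctl$b_max, E),
             if (spec$gamma_free) ctl$gamma_max,
             if (spec$eps_free) 1,
             if (spec$eps_early_free) 1,
             if (theta_free) 0.5)

  build_model <- function(par) {
    par <- pmin(pmax(par, lower), upper)  # optim's finite differences may poke past bounds
    tr <- tree
    tr$edge.length <- par[seq_len(E)]
    i <- E
    gamma <- if (spec$gamma_free) par[i <- i + 1L] else 0
    eps <- if (spec$eps_free) par[i <- i + 1L] else 1
    eps_early <- if (spec$eps_early_free) par[i <- i + 1L] else NULL
    th <- if (theta_free) par[i <- i + 1L] else theta
    loss_model(tr, gamma = gamma, epsilon = eps, theta = th,
               epsilon_early = eps_early,
               early_edges = if (spec$eps_early_free) early_edges)
  }
  negll <- function(par) {
    ll <- sequence_loglik(pillars, build_model(par))
    if (!is.finite(ll)) 1e12 else -ll
  }

  b0 <- if (!is.null(tree$edge.length) && all(tree$edge.length > 0))
    pmin(pmax(tree$edge.length, 1e-3), ctl$b_max) else rep(0.3, E)
  pick <- function(key, default) if (is.null(init[[key]])) default else init[[key]]
  start0 <- c(b0,
              if (spec$gamma_free) pick("gamma", 0.1),
              if (spec$eps_free) pick("epsilon", 0.7),
              if (spec$eps_early_free) pick("epsilon_early", 0.7),
              if (theta_free) pick("theta", 0.01))
  start0 <- pmin(pmax(start0, lower), upper)
  set.seed(as.integer(seed))
  starts <- list(start0)
  for (r in seq_len(restarts))
    starts[[r + 1L]] <- pmin(pmax(start0 * exp(stats::rnorm(length(start0), 0, 0.5)),
                                  lower), upper)

  best <- NULL
  for (st in starts) {
    ## finite-difference steps must resolve theta (~1e-2 scale); optim's
    ## default 1e-3 step is too coarse and stalls convergence
    nd <- rep(1e-5, length(st))
    o <- stats::optim(st, negll, method = "L-BFGS-B", lower = lower, upper = upper,
                      control = list(maxit = ctl$maxit, factr = 1e8, ndeps = nd))
    ## polish by re-invocation until the likelihood stops moving (L-BFGS-B
    ## occasionally halts early; restarting from its endpoint recovers)
    for (round in 1:5) {
      o2 <- stats::optim(o$par, negll, method = "L-BFGS-B", lower = lower,
                         upper = upper,
                         control = list(maxit = 2L * ctl$maxit, factr = 1e6,
                                        ndeps = nd))
      moved <- o$value - o2$value
      if (o2$value <= o$value) o <- o2
      if (moved < 1e-4) { o$convergence <- 0L; break }
    }
    if (is.null(best) || o$value < best$value) best <- o
  }

  par <- stats::setNames(pmin(pmax(best$par, lower), upper), par_names)
  model <- build_model(par)
  structure(list(family = spec$family, logLik = -best$value,
                 gamma = model$gamma, epsilon = model$epsilon,
                 epsilon_early = model$epsilon_early, theta = model$theta,
                 branch_lengths = model$tree$edge.length,
                 model = model, df = length(par),
                 convergence = best$convergence, seed = as.integer(seed)),
            class = "wgd_fit")
}

#' @export
print.wgd_fit <- function(x, ...) {
  cat(sprintf("wgd_fit [WGD-%s]: logLik = %.4f (%d free parameters)\n",
              x$family, x$logLik, x$df))
  cat(sprintf("  gamma = %.4f, epsilon = %.4f%s, theta = %.5f\n",
              x$gamma, x$epsilon,
              if (!is.null(x$epsilon_early))
                sprintf(" (early: %.4f)", x$epsilon_early) else "",
              x$theta))
  if (x$convergence != 0) cat("  WARNING: optimiser did not report convergence\n")
  invisible(x)
}

#' @export
logLik.wgd_fit <- function(object, ...) {
  structure(object$logLik, df = object$df, class = "logLik")
}

#' Likelihood ratio test between nested model fits
#'
#' Compares two nested fits by the statistic `2 (lnL_full - lnL_nested)`
#' against the upper tail of a chi-square distribution. Where the nested
#' model pins `epsilon` at its boundary value 1 the plain chi-square
#' p-value is conservative; it is reported as-is, matching common practice.
#'
#' @param nested,fuller `wgd_fit` objects for the nested and the fuller
#'   family.
#' @param df degrees of freedom; defaults to the difference in free
#'   parameter counts.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
lrt <- function(nested, fuller, df = NULL) {
  stopifnot(inherits(nested, "wgd_fit"), inherits(fuller, "wgd_fit"))
  if (is.null(df)) df <- fuller$df - nested$df
  if (df < 1L) stop("`fuller` must have more free parameters than `nested`", call. = FALSE)
  stat <- 2 * (fuller$logLik - nested$logLik)
  if (stat < -0.1)
    stop("fuller model fits worse than nested beyond numerical tolerance; ",
         "optimisation likely failed", call. = FALSE)
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Fit a model family on every rooted topology
#'
#' Enumerates all rooted binary topologies over the pillar genomes (3 for
#' three taxa, 15 for four), fits the requested family on each, and ranks
#' them by maximised log-likelihood. Ties are broken by parameter count and
#' then by the lexicographic Newick string.
#'
#' @inheritParams fit_model
#' @param max_taxa safety cap on the number of taxa (default 5; the count
#'   of rooted topologies grows as (2n - 3)!!).
#' @param ... passed to [fit_model()].
#' @return List with `results` (data frame: `rank`, `newick`, `logLik`,
#'   `gamma`, `epsilon`, `theta`) and `fits` (the ranked `wgd_fit`
#'   objects).
#' @export
topology_sweep <- function(pillars, family = "bf", max_taxa = 5L, seed = 1L, ...) {
  stopifnot(inherits(pillars, "pillar_set"))
  n <- n_genomes(pillars)
  if (n < 2L) stop("need at least two genomes", call. = FALSE)
  if (n > max_taxa)
    stop(sprintf("topology sweep capped at %d taxa (%d requested)", max_taxa, n),
         call. = FALSE)
  trees <- phangorn::allTrees(n, rooted = TRUE, tip.label = pillars$genomes)
  fits <- lapply(trees, function(tr) {
    tr$edge.length <- rep(0.3, nrow(tr$edge))
    fit_model(pillars, tr, family = family, seed = seed, ...)
  })
  newicks <- vapply(fits, function(f) ape::write.tree(f$model$tree), "")
  ll <- vapply(fits, function(f) f$logLik, 0)
  dfs <- vapply(fits, function(f) f$df, 0L)
  ord <- order(-ll, dfs, newicks)
  res <- data.frame(rank = seq_along(ord), newick = newicks[ord],
                    logLik = ll[ord],
                    gamma = vapply(fits, function(f) f$gamma, 0)[ord],
                    epsilon = vapply(fits, function(f) f$epsilon, 0)[ord],
                    theta = vapply(fits, function(f) f$theta, 0)[ord])
  list(results = res, fits = fits[ord])
}

#' Per-block estimates of the fractionation bias
#'
#' Re-estimates `epsilon` separately within each subgenome block (from
#' [block_segmentation()]), holding every other parameter at the supplied
#' global fit's MLE. Blocks smaller than `min_pillars` are skipped. A
#' genome-wide bias should give per-block estimates scattered around the
#' global one.
#'
#' @param pillars a [pillar_set()].
#' @param blocks data frame from [block_segmentation()].
#' @param fit a global `wgd_fit` (family with `epsilon` free).
#' @param min_pillars minimum block size to refit (default 100, as only
#'   large blocks carry enough losses to inform `epsilon`).
#' @return Data frame: `block`, `start`, `end`, `n_pillars`, `epsilon`,
#'   `logLik`.
#' @export
fit_blocks <- function(pillars, blocks, fit, min_pillars = 100L) {
  stopifnot(inherits(pillars, "pillar_set"), inherits(fit, "wgd_fit"))
  keep <- blocks$n_pillars >= min_pillars
  if (any(!keep))
    message(sum(!keep), " block(s) below the ", min_pillars, "-pillar minimum skipped")
  blocks <- blocks[keep, , drop = FALSE]
  out <- lapply(seq_len(nrow(blocks)), function(i) {
    sub <- pillars[blocks$start[i]:blocks$end[i]]
    f <- function(eps) {
      mod <- fit$model
      mod$epsilon <- eps
      sequence_loglik(sub, mod)
    }
    o <- stats::optimize(f, interval = c(0, 1), maximum = TRUE, tol = 1e-5)
    data.frame(block = blocks$block[i], start = blocks$start[i],
               end = blocks$end[i], n_pillars = blocks$n_pillars[i],
               epsilon = o$maximum, logLik = o$objective)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
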