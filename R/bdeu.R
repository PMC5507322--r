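#' Scoring settings for Bayesian-network structure learning
#'
#' BDeu (Bayesian Dirichlet equivalent uniform) marginal likelihood with an
#' equivalent sample size `ess`, a parent-count cap, and a structure prior
#' that is either uniform over DAGs or penalises each edge by `kappa` on the
#' log scale (prior proportional to `exp(-kappa * edges)`).
#'
#' @param ess equivalent sample size of the Dirichlet prior; must be > 0.
#'   Default 1, the common weak-prior choice.
#' @param max_parents maximum number of parents per node (default 4, needed
#'   for tractability at diseasome scale).
#' @param structure_prior `"uniform"` or `"edge_penalty"`.
#' @param kappa per-edge log penalty, used when
#'   `structure_prior == "edge_penalty"`.
#' @return a list of class `bdmm_score_settings`.
#' @export
score_settings <- function(ess = 1, max_parents = 4,
                           structure_prior = c("uniform", "edge_penalty"),
                           kappa = 0) {
  if (!is.numeric(ess) || length(ess) != 1L || ess <= 0)
    stop("ess must be a positive number")
  stopifnot(max_parents >= 0)
  structure_prior <- match.arg(structure_prior)
  if (structure_prior == "uniform") kappa <- 0
  structure(list(ess = ess, max_parents = as.integer(max_parents),
                 structure_prior = structure_prior, kappa = kappa),
            class = "bdmm_score_settings")
}

# Coerce a cohort / data.frame / matrix of small non-negative integers into
# the 0-based integer matrix + arity vector used by the scorers.
as_model_matrix <- function(x) {
  if (inherits(x, "bdmm_cohort")) x <- x$data
  m <- as.matrix(x)
  storage.mode(m) <- "integer"
  if (nrow(m) > 0 && (anyNA(m) || any(m < 0L)))
    stop("model data must be complete non-negative integers")
  arity <- pmax(apply(m, 2L, function(col) {
    if (length(col) == 0L) 2L else max(col) + 1L
  }), 2L)
  if (nrow(m) == 0L) arity <- rep(2L, ncol(m))
  list(data = m, arity = as.integer(arity), vars = colnames(m))
}

#' Family sufficient statistics
#'
#' Counts of the child's states for every joint parent configuration; the
#' sufficient statistics of the BDeu family score.
#'
#' @param x cohort, data.frame or integer matrix of discrete variables.
#' @param child child column name.
#' @param parents character vector of parent column names (may be empty).
#' @return matrix with one row per parent configuration and one column per
#'   child state; rows ordered by mixed-radix parent index.
#' @export
family_counts <- function(x, child, parents = character()) {
  mm <- as_model_matrix(x)
  idx <- match(c(child, parents), mm$vars)
  if (anyNA(idx)) stop("unknown column(s): ",
                       paste(c(child, parents)[is.na(idx)], collapse = ", "))
  r <- mm$arity[idx[1L]]
  pa <- idx[-1L]
  q <- if (length(pa)) prod(mm$arity[pa]) else 1L
  counts <- matrix(0L, nrow = q, ncol = r)
  if (nrow(mm$data) > 0L) {
    cfg <- rep(0L, nrow(mm$data))
    stride <- 1L
    for (p in pa) {
      cfg <- cfg + mm$data[, p] * stride
      stride <- stride * mm$arity[p]
    }
    tab <- table(factor(cfg, levels = 0:(q - 1L)),
                 factor(mm$data[, idx[1L]], levels = 0:(r - 1L)))
    counts <- matrix(as.integer(tab), nrow = q, ncol = r)
  }
  counts
}

#' BDeu family log marginal likelihood (reference implementation)
#'
#' Computes the log Dirichlet-multinomial marginal likelihood of one family
#' (child plus parent set) under the BDeu prior with hyperparameters
#' `alpha_jk = ess / (r * q)`.  This R implementation is the reference
#' route; the MCMC sampler carries its own compiled scorer, validated
#' against this one in the tests.
#'
#' @param counts a family count matrix from [family_counts()] (parent
#'   configurations in rows, child states in columns).
#' @param settings a [score_settings()] object.
#' @return log marginal likelihood contribution (0 for empty data).
#' @export
#' @examples
#' # binary child, no parents, three 1s and one 0: likelihood 5/128
#' exp(bdeu_family_score(matrix(c(1L, 3L), nrow = 1), score_settings(ess = 1)))
bdeu_family_score <- function(counts, settings = score_settings()) {
  stopifnot(inherits(settings, "bdmm_score_settings"))
  q <- nrow(counts); r <- ncol(counts)
  aj <- settings$ess / q
  ajk <- settings$ess / (q * r)
  s <- 0
  for (j in seq_len(q)) {
    Nj <- sum(counts[j, ])
    if (Nj == 0L) next
    s <- s + lgamma(aj) - lgamma(aj + Nj) +
      sum(lgamma(ajk + counts[j, ]) - lgamma(ajk))
  }
  s
}

#' Total log score of a DAG on a cohort
#'
#' Decomposable sum of BDeu family scores plus the log structure-prior
#' term.  Family scores are cached per (child, parent set) in `cache`
#' (an environment), so repeated scoring during search touches each family
#' once.
#'
#' @param dag a `bdmm_dag` over (a subset of) the cohort columns.
#' @param x cohort, data.frame or integer matrix.
#' @param settings a [score_settings()] object.
#' @param cache optional environment used as score cache across calls.
#' @return total log score (log marginal likelihood + log prior).
#' @export
total_score <- function(dag, x, settings = score_settings(), cache = NULL) {
  over <- vapply(dag$parents, length, 1L) > settings$max_parents
  if (any(over))
    stop("node(s) exceed max_parents: ",
         paste(dag$nodes[over], collapse = ", "))
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  s <- 0
  for (v in dag$nodes) {
    key <- paste(v, paste(sort(dag$parents[[v]]), collapse = ","), sep = "|")
    if (is.null(cache[[key]]))
      cache[[key]] <- bdeu_family_score(
        family_counts(x, v, dag$parents[[v]]), settings)
    s <- s + cache[[key]]
  }
  s - settings$kappa * nrow(dag_edges(dag))
}

mask_to_parents <- function(mask, vars) vars[bitwAnd(mask, bitwShiftL(1L, seq_along(vars) - 1L)) != 0L]

#' Exact feature posteriors by full DAG enumeration
#'
#' Brute-force Bayesian model averaging over every DAG (respecting
#' `max_parents`) for at most 5 variables: 29,281 DAGs at n = 5.  Used as
#' the oracle against which the MCMC sampler is validated.  Posteriors are
#' computed with log-sum-exp stabilisation.
#'
#' @param x cohort, data.frame or integer matrix with at most 5 columns.
#' @param settings a [score_settings()] object.
#' @return list with symmetric matrices `edge` and `association` (marginal
#'   d-connection) and the number of enumerated DAGs `n_dags`.
#' @export
exact_feature_posteriors <- function(x, settings = score_settings()) {
  mm <- as_model_matrix(x)
  n <- ncol(mm$data)
  if (n > 5L)
    stop("exact enumeration is limited to 5 variables (29,281 DAGs); ",
         "got ", n, " - use the MCMC sampler instead")
  vars <- mm$vars
  masks <- cpp_enumerate_dags(n, settings$max_parents)
  # family score per (child, parent-mask), computed once
  fam <- matrix(NA_real_, nrow = n, ncol = 2L^n)
  for (v in seq_len(n)) {
    for (mask in unique(masks[, v])) {
      counts <- family_counts(mm$data, vars[v], mask_to_parents(mask, vars))
      fam[v, mask + 1L] <- bdeu_family_score(counts, settings)
    }
  }
  nd <- nrow(masks)
  log_scores <- numeric(nd)
  for (d in seq_len(nd)) {
    s <- 0
    for (v in seq_len(n)) s <- s + fam[v, masks[d, v] + 1L]
    log_scores[d] <- s
  }
  if (settings$kappa != 0) {
    n_edges <- rowSums(matrix(vapply(as.integer(masks), popcount32, 1L),
                              nrow = nd))
    log_scores <- log_scores - settings$kappa * n_edges
  }
  w <- exp(log_scores - max(log_scores))
  w <- w / sum(w)
  edge <- matrix(0, n, n, dimnames = list(vars, vars))
  assoc <- matrix(0, n, n, dimnames = list(vars, vars))
  for (d in seq_len(nd)) {
    pm <- masks[d, ]
    anc <- ancestor_masks(pm, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      has_edge <- bitwAnd(pm[j], bitwShiftL(1L, i - 1L)) != 0L ||
        bitwAnd(pm[i], bitwShiftL(1L, j - 1L)) != 0L
      if (has_edge) edge[i, j] <- edge[i, j] + w[d]
      if (bitwAnd(anc[i], anc[j]) != 0L) assoc[i, j] <- assoc[i, j] + w[d]
    }
  }
  edge <- edge + t(edge)
  assoc <- assoc + t(assoc)
  list(edge = edge, association = assoc, n_dags = nd)
}

popcount32 <- function(x) sum(bitwAnd(x, bitwShiftL(1L, 0:30)) != 0L)

# ancestor-or-self bitmasks from per-node parent masks (marginal
# d-connection holds iff two nodes share an ancestor, themselves included)
ancestor_masks <- function(parent_masks, n) {
  anc <- bitwShiftL(1L, seq_len(n) - 1L)
  repeat {
    changed <- FALSE
    for (v in seq_len(n)) {
      m <- anc[v]
      pm <- parent_masks[v]
      for (u in seq_len(n)) {
        if (bitwAnd(pm, bitwShiftL(1L, u - 1L)) != 0L)
          m <- bitwOr(m, anc[u])
      }
      if (m != anc[v]) { anc[v] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  anc
}

#' Exact posterior of a single structural feature
#'
#' Convenience wrapper around [exact_feature_posteriors()] returning the
#' posterior of one feature for one pair.
#'
#' @inheritParams exact_feature_posteriors
#' @param feature `"edge"` or `"association"`.
#' @param x_var,y_var the pair of variable names.
#' @return posterior probability in \[0, 1\].
#' @export
exact_feature_posterior <- function(x, feature = c("edge", "association"),
                                    x_var, y_var,
                                    settings = score_settings()) {
  feature <- match.arg(feature)
  post <- exact_feature_posteriors(x, settings)
  post[[feature]][x_var, y_var]
}
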