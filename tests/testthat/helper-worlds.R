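# Shared fixtures: hand-built worlds and independent oracles.
# Everything is generated in code; no stored data.

# wrap a plain data.frame (0/1 diseases [+ sex, age]) as a cohort
make_cohort <- function(df, onset = NULL, age_years = NULL) {
  if (!"sex" %in% names(df)) df[["sex"]] <- integer(nrow(df))
  if (!"age" %in% names(df)) df[["age"]] <- integer(nrow(df))
  diseases <- setdiff(names(df), c("sex", "age"))
  roles <- stats::setNames(
    c(rep("disease", length(diseases)), "sex", "age"),
    c(diseases, "sex", "age"))
  for (col in names(df)) df[[col]] <- as.integer(df[[col]])
  structure(list(data = df[c(diseases, "sex", "age")],
                 age_years = age_years, onset = onset, roles = roles),
            class = "bdmm_cohort")
}

# chain D1 -> D2 -> ... -> Dk with equal marginal prevalence and constant
# positive edge effect (log-odds); no sex/age parents
chain_bn <- function(k, prevalence = 0.02, effect = 2,
                     n_subjects = 20000, seed = 1) {
  nodes <- sprintf("D%02d", seq_len(k))
  parents <- stats::setNames(vector("list", k), nodes)
  beta <- list()
  for (i in 2:k) {
    parents[[nodes[i]]] <- nodes[i - 1L]
    beta[[nodes[i]]] <- stats::setNames(effect, nodes[i - 1L])
  }
  d <- dag(c(nodes, "sex", "age"), parents)
  ground_truth_bn(d, stats::setNames(rep(prevalence, k), nodes), beta,
                  spec = simulation_spec(n_nodes = k,
                                         n_subjects = n_subjects,
                                         seed = seed))
}

# independent binary columns, used as a null world
independent_cohort <- function(n_vars, n_subjects, prevalence = 0.2,
                               seed = 1) {
  set.seed(seed)
  df <- as.data.frame(stats::setNames(lapply(seq_len(n_vars), function(i)
    as.integer(stats::runif(n_subjects) < prevalence)),
    sprintf("V%d", seq_len(n_vars))))
  df
}

# random DAG over n generic nodes (no parent cap), for d-separation tests
random_test_dag <- function(n, p = 0.4) {
  nodes <- LETTERS[seq_len(n)]
  ord <- sample(nodes)
  parents <- stats::setNames(vector("list", n), nodes)
  for (k in seq_len(n)[-1]) {
    pred <- ord[seq_len(k - 1L)]
    parents[[ord[k]]] <- pred[stats::runif(k - 1L) < p]
  }
  dag(nodes, parents)
}

# brute-force d-separation oracle: enumerate all simple paths in the
# skeleton and test head-to-head activeness directly
dsep_oracle <- function(dag_obj, x, y, given = character()) {
  nodes <- dag_obj$nodes
  is_parent <- function(u, v) u %in% dag_obj$parents[[v]]
  nbrs <- function(v) union(
    dag_obj$parents[[v]],
    nodes[vapply(nodes, function(u) is_parent(v, u), TRUE)])
  descendants <- function(v) {
    seen <- v; frontier <- v
    while (length(frontier)) {
      nxt <- unique(unlist(lapply(frontier, function(f)
        nodes[vapply(nodes, function(u) is_parent(f, u), TRUE)])))
      frontier <- setdiff(nxt, seen)
      seen <- c(seen, frontier)
    }
    seen
  }
  active_path <- function(path) {
    if (length(path) == 2L) return(TRUE)
    for (i in 2:(length(path) - 1L)) {
      v <- path[i]
      collider <- is_parent(path[i - 1L], v) && is_parent(path[i + 1L], v)
      if (collider) {
        if (!any(descendants(v) %in% given)) return(FALSE)
      } else {
        if (v %in% given) return(FALSE)
      }
    }
    TRUE
  }
  found <- FALSE
  walk <- function(path) {
    if (found) return()
    v <- path[length(path)]
    if (v == y) {
      if (active_path(path)) found <<- TRUE
      return()
    }
    for (u in setdiff(nbrs(v), path)) walk(c(path, u))
  }
  walk(x)
  !found
}

# area under the ROC curve of score vs binary truth (rank statistic)
auc_score <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth); n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# upper-triangle pairs of a posterior object as a data.frame
posterior_pairs <- function(post, vars = post$variables) {
  pairs <- utils::combn(vars, 2L)
  data.frame(var1 = pairs[1L, ], var2 = pairs[2L, ],
             edge = post$edge[t(pairs)],
             association = post$association[t(pairs)],
             stringsAsFactors = FALSE)
}
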