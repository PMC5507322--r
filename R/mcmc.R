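#' Configuration of the structure-MCMC run
#'
#' Metropolis-Hastings random walk over DAGs with single-edge
#' add/delete/reverse moves.  Defaults (5e5 iterations, 1e5 burn-in,
#' thinning 100, 2 chains) are engineering choices sized for up to ~250
#' variables on one CPU; they are echoed into every output.
#'
#' @param iterations total MH iterations per chain.
#' @param burn_in iterations discarded before feature accumulation.
#' @param thinning keep every `thinning`-th post-burn-in sample.
#' @param n_chains number of independent chains (default 2; cross-chain
#'   disagreement is the convergence diagnostic).
#' @param seed integer seed; per-chain seeds are derived deterministically.
#' @param hill_climb_init start every chain from a greedy hill-climbed
#'   structure instead of the empty graph (default `TRUE`).  With large
#'   cohorts the structure posterior is sharply peaked and a random-walk
#'   burn-in from the empty graph can trap in a distant local mode;
#'   initialization does not change the stationary distribution.
#' @param settings a [score_settings()] object.
#' @return a list of class `bdmm_mcmc_config`.
#' @export
mcmc_config <- function(iterations = 5e5, burn_in = 1e5, thinning = 100,
                        n_chains = 2, seed = 1, hill_climb_init = TRUE,
                        settings = score_settings()) {
  stopifnot(burn_in < iterations, thinning >= 1, n_chains >= 1,
            inherits(settings, "bdmm_score_settings"))
  structure(list(iterations = as.double(iterations),
                 burn_in = as.double(burn_in),
                 thinning = as.integer(thinning),
                 n_chains = as.integer(n_chains),
                 seed = as.integer(seed),
                 hill_climb_init = isTRUE(hill_climb_init),
                 settings = settings),
            class = "bdmm_mcmc_config")
}

# All valid single-edge moves from a DAG state (R reference route).
# Each move is list(type, from, to); reversals are encoded on the current
# edge direction (from -> to becomes to -> from).
dag_moves <- function(dag, max_parents = 4L) {
  moves <- list()
  npar <- vapply(dag$parents, length, 1L)
  has_path <- function(a, b) {
    # directed path a ~> b of length >= 1
    frontier <- dag_children(dag)[[a]]
    seen <- character(0)
    while (length(frontier)) {
      if (b %in% frontier) return(TRUE)
      seen <- c(seen, frontier)
      frontier <- setdiff(
        unique(unlist(dag_children(dag)[frontier], use.names = FALSE)), seen)
    }
    FALSE
  }
  for (u in dag$nodes) for (v in dag$nodes) {
    if (u == v) next
    if (u %in% dag$parents[[v]]) {
      moves[[length(moves) + 1L]] <- list(type = "delete", from = u, to = v)
      if (npar[[u]] < max_parents) {
        tmp <- dag
        tmp$parents[[v]] <- setdiff(tmp$parents[[v]], u)
        ok <- !local({
          frontier <- dag_children(tmp)[[u]]
          seen <- character(0)
          found <- FALSE
          while (length(frontier) && !found) {
            if (v %in% frontier) found <- TRUE
            seen <- c(seen, frontier)
            frontier <- setdiff(
              unique(unlist(dag_children(tmp)[frontier], use.names = FALSE)),
              seen)
          }
          found
        })
        if (ok)
          moves[[length(moves) + 1L]] <- list(type = "reverse", from = u,
                                              to = v)
      }
    } else if (!(v %in% dag$parents[[u]]) && npar[[v]] < max_parents &&
               !has_path(v, u)) {
      moves[[length(moves) + 1L]] <- list(type = "add", from = u, to = v)
    }
  }
  moves
}

apply_move <- function(dag, move) {
  if (move$type == "add") {
    dag$parents[[move$to]] <- c(dag$parents[[move$to]], move$from)
  } else if (move$type == "delete") {
    dag$parents[[move$to]] <- setdiff(dag$parents[[move$to]], move$from)
  } else {
    dag$parents[[move$to]] <- setdiff(dag$parents[[move$to]], move$from)
    dag$parents[[move$from]] <- c(dag$parents[[move$from]], move$to)
  }
  dag
}

#' Propose a single-edge structure move
#'
#' Draws uniformly among all valid edge additions, deletions and reversals
#' (candidates are acyclic and respect `max_parents`) and returns the
#' candidate together with the log Hastings ratio
#' `log |N(state)| - log |N(candidate)|`.  A state with no valid move
#' yields a stay proposal with ratio 0.
#'
#' @param state a `bdmm_dag`.
#' @param max_parents parent cap.
#' @return list with `dag`, `log_hastings`, `move` (`NULL` for stay).
#' @export
propose_move <- function(state, max_parents = 4L) {
  moves <- dag_moves(state, max_parents)
  if (!length(moves))
    return(list(dag = state, log_hastings = 0, move = NULL))
  m <- moves[[sample.int(length(moves), 1L)]]
  cand <- apply_move(state, m)
  n_cand <- length(dag_moves(cand, max_parents))
  list(dag = cand,
       log_hastings = log(length(moves)) - log(max(n_cand, 1L)),
       move = m)
}

#' One Metropolis-Hastings step over structures
#'
#' Proposes a move with [propose_move()] and accepts with probability
#' `min(1, exp(delta_score + log_hastings))`; only the changed families'
#' scores are recomputed (via the shared cache of [total_score()]).
#'
#' @param state a `bdmm_dag`.
#' @param x cohort or data used for scoring.
#' @param settings a [score_settings()] object.
#' @param cache score-cache environment (create once per run).
#' @return list with `dag`, `accepted`, `log_score`.
#' @export
mh_step <- function(state, x, settings = score_settings(),
                    cache = new.env(parent = emptyenv())) {
  prop <- propose_move(state, settings$max_parents)
  s_old <- total_score(state, x, settings, cache)
  if (is.null(prop$move))
    return(list(dag = state, accepted = FALSE, log_score = s_old))
  s_new <- total_score(prop$dag, x, settings, cache)
  if (log(runif(1)) < (s_new - s_old) + prop$log_hastings)
    list(dag = prop$dag, accepted = TRUE, log_score = s_new)
  else
    list(dag = state, accepted = FALSE, log_score = s_old)
}

#' Run structure-MCMC chains and average the structural features
#'
#' Runs `n_chains` independent chains of the compiled sampler, thins each,
#' and model-averages two indicator features per pair: presence of an edge
#' in any orientation (the direct, "co=morbidity" feature) and marginal
#' d-connection (the structural-association feature).  Because an edge
#' implies d-connection, the association posterior dominates the edge
#' posterior pair by pair, per sample.  Sex and age participate as
#' ordinary nodes.
#'
#' @param cohort a `bdmm_cohort` (diseases binary; `age` may have 3
#'   levels) or data.frame of small integers.
#' @param config an [mcmc_config()].
#' @return an object of class `bdmm_posteriors`: list with `variables`,
#'   `edge`, `association` (symmetric matrices), `diagnostics` (max
#'   absolute cross-chain disagreement per feature matrix), `chains`
#'   (per-chain summaries) and `config`.
#' @export
run_chains <- function(cohort, config = mcmc_config()) {
  stopifnot(inherits(config, "bdmm_mcmc_config"))
  mm <- as_model_matrix(cohort)
  if (inherits(cohort, "bdmm_cohort")) {
    for (d in cohort_diseases(cohort))
      if (!all(cohort$data[[d]] %in% 0:1))
        stop("non-binary disease column: ", d)
  }
  st <- config$settings
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    chains[[ch]] <- cpp_structure_mcmc(
      mm$data, mm$arity, st$ess, st$max_parents, st$kappa,
      config$iterations, config$burn_in, config$thinning,
      config$seed * 1000 + ch, config$hill_climb_init)
  }
  nv <- ncol(mm$data)
  avg <- function(field) {
    m <- Reduce(`+`, lapply(chains, `[[`, field)) / length(chains)
    dimnames(m) <- list(mm$vars, mm$vars)
    m
  }
  disagree <- function(field) {
    if (length(chains) < 2L) return(0)
    rng <- 0
    for (i in seq_along(chains)) for (j in seq_along(chains))
      if (i < j)
        rng <- max(rng, max(abs(chains[[i]][[field]] - chains[[j]][[field]])))
    rng
  }
  structure(list(
    variables = mm$vars,
    edge = avg("edge"),
    association = avg("association"),
    diagnostics = c(edge = disagree("edge"),
                    association = disagree("association")),
    chains = lapply(chains, function(c0)
      c0[c("n_samples", "acceptance_rate", "final_log_score")]),
    config = config), class = "bdmm_posteriors")
}

#' @export
print.bdmm_posteriors <- function(x, ...) {
  cat("bdmm_posteriors over", length(x$variables), "variables;",
      "max cross-chain disagreement:",
      sprintf("edge %.4f, association %.4f", x$diagnostics[["edge"]],
              x$diagnostics[["association"]]), "\n")
  invisible(x)
}

#' Write posterior matrices as long-format TSV
#'
#' One row per unordered pair with both posteriors and the cross-chain
#' diagnostic; config echoed as `#`-prefixed header lines.
#'
#' @param post a `bdmm_posteriors`.
#' @param path output path.
#' @export
write_posteriors_tsv <- function(post, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- post$config
  writeLines(sprintf(
    "# iterations=%g burn_in=%g thinning=%d n_chains=%d seed=%d ess=%g max_parents=%d",
    cfg$iterations, cfg$burn_in, cfg$thinning, cfg$n_chains, cfg$seed,
    cfg$settings$ess, cfg$settings$max_parents), con)
  v <- post$variables
  pairs <- utils::combn(v, 2L)
  df <- data.frame(var1 = pairs[1L, ], var2 = pairs[2L, ],
                   edge_posterior = post$edge[t(pairs)],
                   association_posterior = post$association[t(pairs)],
                   diagnostic_edge = rep(post$diagnostics[["edge"]],
                                         ncol(pairs)))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write posterior matrices as JSON
#' @inheritParams write_posteriors_tsv
#' @export
write_posteriors_json <- function(post, path) {
  cfg <- post$config
  jsonlite::write_json(list(
    variables = post$variables,
    edge = post$edge, association = post$association,
    diagnostics = as.list(post$diagnostics),
    config = list(iterations = cfg$iterations, burn_in = cfg$burn_in,
                  thinning = cfg$thinning, n_chains = cfg$n_chains,
                  seed = cfg$seed, ess = cfg$settings$ess,
                  max_parents = cfg$settings$max_parents)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
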