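#' Specification of a synthetic multimorbidity world
#'
#' Collects the knobs of the cohort simulator.  Defaults mirror the scale
#' of a large population cohort where affordable on one CPU: tens of
#' diseases, 10^4 subjects, lifetime prevalences between 1 permille and
#' 30%, and absolute log-odds effects of 1-2.5 between directly related
#' diseases.
#'
#' @param n_nodes number of disease variables.
#' @param n_subjects cohort size.
#' @param max_parents cap on parents per disease in the ground-truth DAG.
#' @param edge_density expected fraction of the `n(n-1)/2` possible
#'   disease-disease edges that are present.
#' @param prevalence_range target marginal prevalence interval.
#' @param effect_range interval for absolute log-odds parent coefficients.
#' @param confounder_fraction share of diseases that additionally receive
#'   sex and/or age as parents.
#' @param p_order probability that a parent disease's onset precedes its
#'   child's when both are present (see [simulate_onsets()]).
#' @param min_onset_age earliest possible onset age in years.
#' @param seed integer seed; the whole module is bit-reproducible given
#'   (spec, seed).
#' @return a list of class `bdmm_simspec`.
#' @export
simulation_spec <- function(n_nodes = 20, n_subjects = 10000,
                            max_parents = 3, edge_density = 0.1,
                            prevalence_range = c(0.001, 0.3),
                            effect_range = c(1, 2.5),
                            confounder_fraction = 0.3,
                            p_order = 0.8, min_onset_age = 10, seed = 1) {
  stopifnot(n_nodes >= 1, n_subjects >= 1, max_parents >= 0,
            edge_density >= 0, edge_density <= 1,
            length(prevalence_range) == 2L,
            prevalence_range[1] > 0, prevalence_range[2] < 1,
            prevalence_range[1] <= prevalence_range[2],
            length(effect_range) == 2L, effect_range[1] >= 0,
            effect_range[1] <= effect_range[2],
            confounder_fraction >= 0, confounder_fraction <= 1,
            p_order >= 0, p_order <= 1)
  structure(list(n_nodes = as.integer(n_nodes),
                 n_subjects = as.integer(n_subjects),
                 max_parents = as.integer(max_parents),
                 edge_density = edge_density,
                 prevalence_range = prevalence_range,
                 effect_range = effect_range,
                 confounder_fraction = confounder_fraction,
                 p_order = p_order, min_onset_age = min_onset_age,
                 seed = as.integer(seed)),
            class = "bdmm_simspec")
}

#' Sample a random disease DAG
#'
#' Draws a uniformly random topological order, includes each
#' order-compatible edge independently with probability `edge_density`,
#' and errors when the requested density cannot respect `max_parents`
#' (expected parent count of the most-constrained node above the cap).
#'
#' @param spec a [simulation_spec()].
#' @return a `bdmm_dag` over disease names `D01`, `D02`, ...
#' @export
sample_random_dag <- function(spec) {
  stopifnot(inherits(spec, "bdmm_simspec"))
  set.seed(spec$seed)
  n <- spec$n_nodes
  if (spec$edge_density * (n - 1) > spec$max_parents)
    stop("configuration error: edge_density ", spec$edge_density,
         " incompatible with max_parents ", spec$max_parents,
         " at ", n, " nodes")
  nodes <- sprintf("D%02d", seq_len(n))
  ord <- sample(nodes)
  parents <- setNames(vector("list", n), nodes)
  if (n > 1L) {
    for (k in 2:n) {
      pred <- ord[seq_len(k - 1L)]
      pick <- pred[runif(length(pred)) < spec$edge_density]
      if (length(pick) > spec$max_parents)
        pick <- sample(pick, spec$max_parents)
      parents[[ord[k]]] <- pick
    }
  }
  dag(nodes, parents)
}

#' Attach logistic conditional tables to a disease DAG
#'
#' Builds the ground-truth Bayesian network: each disease gets a logistic
#' conditional probability table, `logit P(d = 1 | pa) = beta0 + sum_j
#' beta_j x_j`, with |beta_j| drawn from `effect_range` with random sign
#' and `beta0` chosen so that, with all parents at their marginal
#' expectations, the prevalence hits a target drawn from
#' `prevalence_range` (log-uniform, emulating the right-skewed prevalence
#' spectrum of real disease registries).  A `confounder_fraction` share of
#' diseases additionally receives sex (binary) and/or age (3-level bin) as
#' parents.
#'
#' @param dag a `bdmm_dag` of diseases from [sample_random_dag()].
#' @param spec the matching [simulation_spec()].
#' @return an object of class `bdmm_bn` with fields `dag` (now including
#'   `sex` and `age` root nodes), `roles`, `beta0`, `beta` and the plug-in
#'   marginal expectations `mu`.
#' @export
sample_cpts <- function(dag, spec) {
  stopifnot(inherits(dag, "bdmm_dag"), inherits(spec, "bdmm_simspec"))
  set.seed(spec$seed + 1L)
  diseases <- dag$nodes
  parents <- dag$parents
  n_conf <- round(spec$confounder_fraction * length(diseases))
  conf <- if (n_conf > 0) sample(diseases, n_conf) else character(0)
  for (v in conf) {
    which_conf <- sample(c("sex", "age", "both"), 1L)
    add <- switch(which_conf, sex = "sex", age = "age", both = c("sex", "age"))
    parents[[v]] <- c(parents[[v]], add)
  }
  nodes <- c("sex", "age", diseases)
  parents$sex <- character(0)
  parents$age <- character(0)
  full <- dag(nodes, parents)
  roles <- setNames(c("sex", "age", rep("disease", length(diseases))), nodes)

  lo <- log(spec$prevalence_range[1]); hi <- log(spec$prevalence_range[2])
  beta0 <- setNames(numeric(length(nodes)), nodes)
  beta <- setNames(vector("list", length(nodes)), nodes)
  mu <- setNames(numeric(length(nodes)), nodes)
  mu["sex"] <- 0.548 # female share of the emulated cohort
  mu["age"] <- 1     # equal-frequency 3-level bin, values 0/1/2
  for (v in setdiff(topo_sort(full), c("sex", "age"))) {
    ps <- full$parents[[v]]
    b <- stats::runif(length(ps), spec$effect_range[1], spec$effect_range[2]) *
      sample(c(-1, 1), length(ps), replace = TRUE)
    names(b) <- ps
    target <- exp(stats::runif(1, lo, hi))
    b0 <- qlogis(target) - sum(b * mu[ps])
    beta0[[v]] <- b0
    beta[[v]] <- b
    mu[[v]] <- target # plug-in marginal used for downstream children
  }
  structure(list(dag = full, roles = roles, beta0 = beta0, beta = beta,
                 mu = mu, spec = spec),
            class = "bdmm_bn")
}

#' Construct a ground-truth network by hand
#'
#' Builds a `bdmm_bn` from an explicit DAG and logistic coefficients, for
#' controlled benchmark worlds (chains, forks, colliders).  Nodes named
#' `sex`/`age` take those roles; every other node is a disease.  Plug-in
#' marginal expectations are propagated in topological order for any node
#' whose `beta0` is given as a target prevalence via `prevalence`.
#'
#' @param dag a `bdmm_dag` (may include `sex` and `age` nodes).
#' @param prevalence named vector of target marginal prevalences per
#'   disease; `beta0` is derived as `qlogis(prevalence) - sum(beta * mu)`.
#' @param beta named list (per child) of named numeric parent
#'   coefficients (log-odds).  Missing entries mean no parents / zero
#'   coefficients.
#' @param spec optional [simulation_spec()] supplying simulator defaults.
#' @return a `bdmm_bn`.
#' @export
ground_truth_bn <- function(dag, prevalence, beta = list(), spec = NULL) {
  stopifnot(inherits(dag, "bdmm_dag"))
  nodes <- dag$nodes
  roles <- setNames(ifelse(nodes == "sex", "sex",
                    ifelse(nodes == "age", "age", "disease")), nodes)
  diseases <- nodes[roles == "disease"]
  stopifnot(all(diseases %in% names(prevalence)))
  if (is.null(spec))
    spec <- simulation_spec(n_nodes = max(length(diseases), 1L))
  mu <- setNames(numeric(length(nodes)), nodes)
  mu["sex"] <- 0.548
  mu["age"] <- 1
  beta0 <- setNames(numeric(length(nodes)), nodes)
  bfull <- setNames(vector("list", length(nodes)), nodes)
  for (v in topo_sort(dag)) {
    if (roles[[v]] != "disease") next
    ps <- dag$parents[[v]]
    b <- setNames(rep(0, length(ps)), ps)
    if (!is.null(beta[[v]])) {
      stopifnot(all(names(beta[[v]]) %in% ps))
      b[names(beta[[v]])] <- beta[[v]]
    }
    beta0[[v]] <- qlogis(prevalence[[v]]) - sum(b * mu[ps])
    bfull[[v]] <- b
    mu[[v]] <- prevalence[[v]]
  }
  structure(list(dag = dag, roles = roles, beta0 = beta0, beta = bfull,
                 mu = mu, spec = spec), class = "bdmm_bn")
}

#' @export
print.bdmm_bn <- function(x, ...) {
  cat("bdmm_bn:", sum(x$roles == "disease"), "diseases + sex + age,",
      nrow(dag_edges(x$dag)), "edges\n")
  invisible(x)
}

#' Simulate a cohort from a ground-truth network
#'
#' Ancestral sampling in topological order: sex is Bernoulli(0.548), raw
#' age in years is piecewise-uniform with tertiles at 60 and 68 (so that
#' equal-frequency binning reproduces the canonical thresholds), and every
#' disease is Bernoulli with its logistic conditional probability.
#'
#' @param bn a `bdmm_bn`.
#' @param n_subjects number of subjects.
#' @param seed integer seed.
#' @return an object of class `bdmm_cohort`: list with `data` (data.frame
#'   of integer columns: diseases 0/1, `sex` 0/1, `age` bin 0/1/2),
#'   `age_years`, `onset` (NULL until [simulate_onsets()]), `roles`.
#' @export
simulate_cohort <- function(bn, n_subjects = bn$spec$n_subjects,
                            seed = bn$spec$seed) {
  stopifnot(inherits(bn, "bdmm_bn"), n_subjects >= 1)
  set.seed(seed)
  n <- as.integer(n_subjects)
  cols <- list()
  cols$sex <- as.integer(runif(n) < bn$mu["sex"])
  seg <- sample.int(3L, n, replace = TRUE)
  age_years <- c(40, 60, 68)[seg] + runif(n) * c(20, 8, 7)[seg]
  cols$age <- bin_age(age_years)
  for (v in setdiff(topo_sort(bn$dag), c("sex", "age"))) {
    eta <- rep(bn$beta0[[v]], n)
    for (p in names(bn$beta[[v]]))
      eta <- eta + bn$beta[[v]][[p]] * cols[[p]]
    cols[[v]] <- as.integer(runif(n) < plogis(eta))
  }
  diseases <- names(bn$roles)[bn$roles == "disease"]
  data <- as.data.frame(cols[c(diseases, "sex", "age")])
  structure(list(data = data, age_years = age_years, onset = NULL,
                 roles = bn$roles), class = "bdmm_cohort")
}

#' @export
print.bdmm_cohort <- function(x, ...) {
  cat("bdmm_cohort:", nrow(x$data), "subjects,",
      length(cohort_diseases(x)), "diseases",
      if (!is.null(x$onset)) "(with onsets)" else "", "\n")
  invisible(x)
}

#' Disease columns of a cohort
#' @param cohort a `bdmm_cohort`.
#' @return character vector of disease column names.
#' @export
cohort_diseases <- function(cohort) {
  intersect(names(cohort$data),
            names(cohort$roles)[cohort$roles == "disease"])
}

#' Simulate disease onset ages
#'
#' For every affected subject an onset age is drawn uniformly between
#' `min_onset_age` and the subject's current age (continuous years, so ties
#' have probability zero).  Then, sweeping ground-truth edges in
#' topological order, each (parent present, child present) pair is forced
#' into causal order with probability `p_order`: the child's onset is
#' redrawn uniformly after the parent's (or, with probability
#' `1 - p_order`, before it).
#'
#' @param cohort a `bdmm_cohort` generated from `bn`.
#' @param bn the generating `bdmm_bn`.
#' @param seed integer seed.
#' @param p_order probability of parent-before-child ordering.
#' @param min_onset_age earliest onset age.
#' @return the cohort with an `onset` matrix (subjects x diseases, `NA`
#'   where unaffected).
#' @export
simulate_onsets <- function(cohort, bn, seed = bn$spec$seed,
                            p_order = bn$spec$p_order,
                            min_onset_age = bn$spec$min_onset_age) {
  stopifnot(inherits(cohort, "bdmm_cohort"), inherits(bn, "bdmm_bn"))
  set.seed(seed + 2L)
  diseases <- cohort_diseases(cohort)
  n <- nrow(cohort$data)
  onset <- matrix(NA_real_, n, length(diseases),
                  dimnames = list(NULL, diseases))
  age <- cohort$age_years
  if (is.null(age)) age <- rep(75, n) # cohort loaded without raw ages
  for (d in diseases) {
    aff <- cohort$data[[d]] == 1L
    onset[aff, d] <- min_onset_age +
      runif(sum(aff)) * (age[aff] - min_onset_age)
  }
  edges <- dag_edges(bn$dag)
  ord <- topo_sort(bn$dag)
  edges <- edges[order(match(edges$to, ord)), , drop = FALSE]
  for (k in seq_len(nrow(edges))) {
    p <- edges$from[k]; ch <- edges$to[k]
    if (!(p %in% diseases) || !(ch %in% diseases)) next
    both <- which(cohort$data[[p]] == 1L & cohort$data[[ch]] == 1L)
    if (!length(both)) next
    ordered <- runif(length(both)) < p_order
    po <- onset[both, p]
    hi <- age[both]
    # redraw the child's onset strictly after (or before) the parent's
    after <- po + runif(length(both)) * pmax(hi - po, 0) + 1e-9
    before <- min_onset_age + runif(length(both)) * pmax(po - min_onset_age, 0)
    onset[both, ch] <- ifelse(ordered, after, before)
  }
  cohort$onset <- onset
  cohort
}

#' Remove disease occurrences recorded after a target disease's onset
#'
#' For every subject affected by `target`, any other disease whose onset is
#' strictly after the target's onset is recoded as absent (its onset
#' cleared).  Diseases without onset information are kept when
#' `keep_missing_onset` is `TRUE` (mirroring the convention of retaining
#' variables such as BMI-derived obesity as preceding the target).
#' Subjects unaffected by the target, or affected without a recorded
#' target onset, are left unchanged.  The operation is idempotent and
#' never increases a disease count.
#'
#' @param cohort a `bdmm_cohort` with onsets.
#' @param target target disease name.
#' @param keep_missing_onset keep diseases with missing onset (default
#'   `TRUE`).
#' @return the filtered cohort.
#' @export
filter_onset_before <- function(cohort, target, keep_missing_onset = TRUE) {
  stopifnot(inherits(cohort, "bdmm_cohort"))
  diseases <- cohort_diseases(cohort)
  if (!target %in% diseases) stop("unknown target disease: ", target)
  if (is.null(cohort$onset) || !target %in% colnames(cohort$onset))
    stop("target disease has no onset column: ", target)
  t_on <- cohort$onset[, target]
  affected <- which(cohort$data[[target]] == 1L & !is.na(t_on))
  for (d in setdiff(diseases, target)) {
    has_onset <- d %in% colnames(cohort$onset)
    for_subj <- affected[cohort$data[[d]][affected] == 1L]
    if (!length(for_subj)) next
    if (!has_onset) {
      if (!keep_missing_onset) cohort$data[[d]][for_subj] <- 0L
      next
    }
    d_on <- cohort$onset[for_subj, d]
    drop <- if (keep_missing_onset) {
      !is.na(d_on) & d_on > t_on[for_subj]
    } else {
      is.na(d_on) | d_on > t_on[for_subj]
    }
    idx <- for_subj[drop]
    cohort$data[[d]][idx] <- 0L
    cohort$onset[idx, d] <- NA_real_
  }
  cohort
}

#' Drop rare diseases
#'
#' Removes disease columns whose prevalence (case count / subjects) is
#' below `min_prevalence`; sex and age are never dropped.
#'
#' @param cohort a `bdmm_cohort`.
#' @param min_prevalence prevalence floor (default 0.001, i.e. 1 permille).
#' @return the filtered cohort; dropped columns reported via `message()`.
#' @export
filter_prevalence <- function(cohort, min_prevalence = 0.001) {
  stopifnot(inherits(cohort, "bdmm_cohort"))
  diseases <- cohort_diseases(cohort)
  n <- nrow(cohort$data)
  prev <- vapply(cohort$data[diseases], function(col) sum(col) / n, 1.0)
  drop <- diseases[prev < min_prevalence]
  if (length(drop)) {
    message("filter_prevalence: dropping ", length(drop), " disease(s): ",
            paste(drop, collapse = ", "))
    cohort$data <- cohort$data[setdiff(names(cohort$data), drop)]
    if (!is.null(cohort$onset))
      cohort$onset <- cohort$onset[, setdiff(colnames(cohort$onset), drop),
                                   drop = FALSE]
    cohort$roles <- cohort$roles[setdiff(names(cohort$roles), drop)]
  }
  cohort
}

#' Bin ages into three categories
#'
#' Fixed mode uses the canonical thresholds (default 60 and 68 years),
#' closed on the left: bin 0 is `age < t1`, bin 1 is `t1 <= age < t2`,
#' bin 2 is `age >= t2`.  Equal-frequency mode computes tertile cut points
#' from the data, again with lower-closed intervals.
#'
#' @param ages numeric vector of non-negative ages in years.
#' @param mode `"fixed"` or `"equal_frequency"`.
#' @param thresholds the two fixed cut points.
#' @return integer vector with values in \{0, 1, 2\}.
#' @export
#' @examples
#' bin_age(c(55, 63, 70)) # 0 1 2
bin_age <- function(ages, mode = c("fixed", "equal_frequency"),
                    thresholds = c(60, 68)) {
  mode <- match.arg(mode)
  stopifnot(all(ages >= 0, na.rm = TRUE), length(thresholds) == 2L,
            thresholds[1] < thresholds[2])
  if (mode == "equal_frequency") {
    s <- sort(ages)
    n <- length(s)
    # left-closed tertile cut points: first elements of bins 1 and 2
    thresholds <- c(s[floor(n / 3) + 1L], s[floor(2 * n / 3) + 1L])
  }
  as.integer(ages >= thresholds[1]) + as.integer(ages >= thresholds[2])
}

#' Code obesity from BMI
#'
#' 1 iff BMI is greater than or equal to 30 kg/m^2.  Missing BMI yields a
#' missing code; the number of such subjects is reported.
#'
#' @param bmi numeric vector of BMI values (kg/m^2), positive.
#' @return integer vector in \{0, 1, NA\}.
#' @export
code_obesity <- function(bmi) {
  stopifnot(all(bmi > 0, na.rm = TRUE))
  if (anyNA(bmi))
    message("code_obesity: ", sum(is.na(bmi)),
            " subject(s) with missing BMI excluded from obesity coding")
  as.integer(bmi >= 30)
}

#' Ground-truth labels for every disease pair
#'
#' Classifies each unordered disease pair of the generating network as
#' `direct` (adjacent), `connected` (non-adjacent but marginally
#' d-connected, i.e. sharing an ancestor, possibly sex/age) or `separated`.
#' These labels drive the structure-recovery benchmarks.
#'
#' @param bn a `bdmm_bn`.
#' @return data.frame with columns `var1`, `var2`, `label`.
#' @export
truth_labels <- function(bn) {
  stopifnot(inherits(bn, "bdmm_bn"))
  diseases <- names(bn$roles)[bn$roles == "disease"]
  pairs <- utils::combn(diseases, 2L)
  label <- character(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    x <- pairs[1L, k]; y <- pairs[2L, k]
    label[k] <- if (edge_feature(bn$dag, x, y)) "direct"
    else if (association_feature(bn$dag, x, y)) "connected"
    else "separated"
  }
  data.frame(var1 = pairs[1L, ], var2 = pairs[2L, ], label = label,
             stringsAsFactors = FALSE)
}

#' Write the ground truth as JSON
#'
#' Serializes the DAG (child to parents), the logistic coefficients and the
#' derived per-pair truth labels.
#'
#' @param bn a `bdmm_bn`.
#' @param path output path.
#' @export
write_ground_truth <- function(bn, path) {
  jsonlite::write_json(
    list(nodes = bn$dag$nodes, roles = as.list(bn$roles),
         parents = bn$dag$parents, beta0 = as.list(bn$beta0),
         beta = lapply(bn$beta, as.list),
         truth = truth_labels(bn)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
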