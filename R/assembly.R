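#' Classify disease-disease relations as direct, mediated or spurious
#'
#' Applies the bimodal-posterior thresholds: a pair is `direct` when its
#' edge posterior exceeds `threshold_high`; among the rest, `mediated`
#' when it is Bonferroni-significant with structural-association posterior
#' at least `assoc_floor`, `parametric_only` when significant but with
#' association posterior below the floor (co-occurrence too weak for the
#' network to capture), and `none` otherwise.  Every pair receives exactly
#' one class.
#'
#' @param posteriors a `bdmm_posteriors` from [run_chains()] (or a list
#'   with `edge` / `association` matrices).
#' @param pairwise a [pairwise_table()] over the same disease pairs.
#' @param threshold_high direct-edge posterior threshold (default 0.95).
#' @param threshold_low lower bimodality threshold (default 0.05), kept in
#'   the output for map building and reporting.
#' @param assoc_floor structural-association floor (default 0.1).
#' @return data.frame with columns `var1`, `var2`, `edge_posterior`,
#'   `association_posterior`, `bonferroni`, `class`.
#' @export
classify_relations <- function(posteriors, pairwise, threshold_high = 0.95,
                               threshold_low = 0.05, assoc_floor = 0.1) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  pv <- intersect(posteriors$variables, unique(c(pairwise$var1,
                                                 pairwise$var2)))
  pw_keys <- key(pairwise$var1, pairwise$var2)
  pairs <- utils::combn(sort(pv), 2L)
  want <- key(pairs[1L, ], pairs[2L, ])
  if (!all(want %in% pw_keys))
    stop("pair universes differ between posteriors and pairwise table")
  idx <- match(want, pw_keys)
  ep <- posteriors$edge[t(pairs)]
  ap <- posteriors$association[t(pairs)]
  bf <- pairwise$bonferroni[idx]
  cls <- ifelse(ep > threshold_high, "direct",
         ifelse(bf & ap >= assoc_floor, "mediated",
         ifelse(bf, "parametric_only", "none")))
  out <- data.frame(var1 = pairs[1L, ], var2 = pairs[2L, ],
                    edge_posterior = ep, association_posterior = ap,
                    bonferroni = bf, class = cls,
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- c(high = threshold_high, low = threshold_low,
                               assoc_floor = assoc_floor)
  out
}

#' Build the multimorbidity map
#'
#' Undirected weighted graph containing every pair whose edge posterior
#' exceeds `cutoff` (default 0.05, the map-membership threshold); the
#' posterior is the edge weight and node prevalences are attached when a
#' cohort is supplied.
#'
#' @param posteriors a `bdmm_posteriors`.
#' @param cutoff posterior cut-off for map membership.
#' @param cohort optional `bdmm_cohort` supplying node prevalences.
#' @return an [igraph::igraph] object with edge attribute `weight` and
#'   graph attribute `cutoff`.
#' @export
build_map <- function(posteriors, cutoff = 0.05, cohort = NULL) {
  v <- posteriors$variables
  g <- igraph::make_empty_graph(n = length(v), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = v)
  pairs <- which(upper.tri(posteriors$edge) & posteriors$edge > cutoff,
                 arr.ind = TRUE)
  if (nrow(pairs)) {
    el <- rbind(v[pairs[, 1L]], v[pairs[, 2L]])
    g <- igraph::add_edges(g, as.vector(el),
                           weight = posteriors$edge[pairs])
  }
  if (!is.null(cohort)) {
    prev <- vapply(v, function(x)
      if (x %in% names(cohort$data)) mean(cohort$data[[x]]) else NA_real_,
      1.0)
    g <- igraph::set_vertex_attr(g, "prevalence", value = prev)
  }
  g <- igraph::set_graph_attr(g, "cutoff", cutoff)
  g
}

#' Ego network around a focus disease
#'
#' Induced subgraph on all nodes within unweighted graph distance
#' `radius` of the focus.  Hub covariates such as sex and age can be
#' dropped first (with all their incident edges) so they do not pull in
#' nodes related to the focus only through them.
#'
#' @param map an [igraph::igraph] from [build_map()].
#' @param focus focus node name.
#' @param radius maximum graph distance (default 2).
#' @param drop_covariates node names removed before the distance
#'   computation (e.g. `c("sex", "age")`).
#' @return the induced [igraph::igraph] subgraph.
#' @export
ego_network <- function(map, focus, radius = 2,
                        drop_covariates = character()) {
  if (!focus %in% igraph::V(map)$name) stop("focus absent from map: ", focus)
  drop_covariates <- setdiff(drop_covariates, focus)
  g <- igraph::delete_vertices(
    map, intersect(drop_covariates, igraph::V(map)$name))
  d <- igraph::distances(g, v = focus, weights = NA)
  keep <- igraph::V(g)$name[d[1L, ] <= radius]
  igraph::induced_subgraph(g, keep)
}

#' Quadrant report of posterior versus parametric significance
#'
#' Counts the four cells of (edge posterior > high threshold) x
#' (Bonferroni significance).  The (direct, not-significant) cell is
#' expected to be empty — every direct relation should also be visible to
#' the pairwise test — and a warning is raised if it is not, as this
#' questions the stability of the posterior landscape.
#'
#' @param classes a [classify_relations()] result.
#' @param threshold_high direct threshold (defaults to the one stored on
#'   `classes`).
#' @return 2x2 integer matrix with dimnames
#'   `direct`/`not_direct` x `significant`/`not_significant`.
#' @export
sanity_quadrant_report <- function(classes,
                                   threshold_high =
                                     attr(classes, "thresholds")[["high"]]) {
  hi <- classes$edge_posterior > threshold_high
  sig <- classes$bonferroni
  m <- matrix(c(sum(hi & sig), sum(hi & !sig),
                sum(!hi & sig), sum(!hi & !sig)),
              nrow = 2L, byrow = TRUE,
              dimnames = list(c("direct", "not_direct"),
                              c("significant", "not_significant")))
  if (m["direct", "not_significant"] > 0L)
    warning(m["direct", "not_significant"],
            " pair(s) with high edge posterior lack parametric ",
            "significance; posterior distribution may be unstable")
  m
}

#' Export a multimorbidity map
#'
#' `write_map_graphml` writes GraphML (via igraph); `write_map_tsv` an
#' edge-list TSV with weight, class and prevalence attributes;
#' `write_map_json` a web-payload-style JSON with `nodes`, `links` and the
#' thresholds.
#'
#' @param map an [igraph::igraph] from [build_map()].
#' @param path output path.
#' @param classes optional [classify_relations()] table used to attach a
#'   `class` attribute per edge.
#' @export
write_map_graphml <- function(map, path, classes = NULL) {
  map <- attach_classes(map, classes)
  igraph::write_graph(map, path, format = "graphml")
  invisible(path)
}

attach_classes <- function(map, classes) {
  if (is.null(classes)) return(map)
  el <- igraph::as_edgelist(map)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  cls <- classes$class[match(key(el[, 1L], el[, 2L]),
                             key(classes$var1, classes$var2))]
  igraph::set_edge_attr(map, "class", value = cls)
}

#' @rdname write_map_graphml
#' @export
write_map_tsv <- function(map, path, classes = NULL) {
  map <- attach_classes(map, classes)
  el <- igraph::as_edgelist(map)
  df <- data.frame(var1 = el[, 1L], var2 = el[, 2L],
                   weight = igraph::E(map)$weight,
                   stringsAsFactors = FALSE)
  if (!is.null(igraph::edge_attr(map, "class")))
    df$class <- igraph::E(map)$class
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map_graphml
#' @export
write_map_json <- function(map, path, classes = NULL) {
  map <- attach_classes(map, classes)
  el <- igraph::as_edgelist(map)
  nodes <- data.frame(id = igraph::V(map)$name, stringsAsFactors = FALSE)
  if (!is.null(igraph::vertex_attr(map, "prevalence")))
    nodes$prevalence <- igraph::V(map)$prevalence
  links <- data.frame(source = el[, 1L], target = el[, 2L],
                      weight = igraph::E(map)$weight,
                      stringsAsFactors = FALSE)
  if (!is.null(igraph::edge_attr(map, "class")))
    links$class <- igraph::E(map)$class
  jsonlite::write_json(list(nodes = nodes, links = links,
                            cutoff = igraph::graph_attr(map, "cutoff")),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
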