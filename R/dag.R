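#' Directed acyclic graph over named variables
#'
#' Light-weight DAG container used for ground-truth structures and for the
#' R-level reference route of the sampler.  Parents are stored as a named
#' list of character vectors; acyclicity is checked on construction.
#'
#' @param nodes character vector of unique node names.
#' @param parents named list mapping a node to the character vector of its
#'   parents. Nodes absent from the list have no parents.
#' @return an object of class `bdmm_dag`.
#' @export
#' @examples
#' d <- dag(c("A", "B", "C"), list(B = "A", C = "B"))
#' dag_edges(d)
dag <- function(nodes, parents = list()) {
  stopifnot(is.character(nodes), !anyDuplicated(nodes))
  full <- setNames(vector("list", length(nodes)), nodes)
  for (v in names(parents)) {
    if (!v %in% nodes) stop("unknown node in parent map: ", v)
    p <- unique(as.character(parents[[v]]))
    if (v %in% p) stop("self-loop at node ", v)
    bad <- setdiff(p, nodes)
    if (length(bad)) stop("unknown parent(s): ", paste(bad, collapse = ", "))
    full[[v]] <- p
  }
  full <- lapply(full, function(p) if (is.null(p)) character(0) else p)
  obj <- structure(list(nodes = nodes, parents = full), class = "bdmm_dag")
  if (is.null(topo_sort(obj))) stop("parent map contains a directed cycle")
  obj
}

#' Topological order of a DAG
#'
#' @param x a `bdmm_dag`.
#' @return character vector of nodes in topological order, or `NULL` if the
#'   graph is cyclic (only reachable from internal callers).
#' @export
topo_sort <- function(x) {
  nodes <- x$nodes
  indeg <- vapply(x$parents[nodes], length, 1L)
  order <- character(0)
  avail <- nodes[indeg == 0L]
  children <- dag_children(x)
  while (length(avail)) {
    v <- avail[[1L]]
    avail <- avail[-1L]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) avail <- c(avail, ch)
    }
  }
  if (length(order) != length(nodes)) return(NULL)
  order
}

dag_children <- function(x) {
  out <- setNames(vector("list", length(x$nodes)), x$nodes)
  for (v in x$nodes) out[[v]] <- character(0)
  for (v in x$nodes) for (p in x$parents[[v]]) out[[p]] <- c(out[[p]], v)
  out
}

#' Edge list of a DAG
#' @param x a `bdmm_dag`.
#' @return data.frame with columns `from`, `to` (one row per directed edge).
#' @export
dag_edges <- function(x) {
  from <- character(0); to <- character(0)
  for (v in x$nodes) {
    p <- x$parents[[v]]
    from <- c(from, p)
    to <- c(to, rep(v, length(p)))
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

#' @export
print.bdmm_dag <- function(x, ...) {
  e <- dag_edges(x)
  cat("bdmm_dag with", length(x$nodes), "nodes and", nrow(e), "edges\n")
  invisible(x)
}

#' Test whether an edge (in any orientation) joins two nodes
#'
#' The structural feature behind the "co=morbidity" (direct) relation: true
#' iff `x -> y` or `y -> x` is present.
#'
#' @param dag a `bdmm_dag`.
#' @param x,y node names, distinct.
#' @return logical flag.
#' @export
edge_feature <- function(dag, x, y) {
  stopifnot(x != y)
  check_nodes(dag, c(x, y))
  (x %in% dag$parents[[y]]) || (y %in% dag$parents[[x]])
}

check_nodes <- function(dag, v) {
  bad <- setdiff(v, dag$nodes)
  if (length(bad)) stop("unknown node(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

ancestors_of <- function(dag, v) {
  # ancestors including v itself
  seen <- v
  frontier <- v
  while (length(frontier)) {
    nxt <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  seen
}

#' d-separation in a DAG
#'
#' Decides whether `x` and `y` are d-separated given a conditioning set,
#' via the ancestral moral graph: restrict to ancestors of \{x, y, Z\},
#' marry co-parents, drop directions, delete Z, and test connectivity.
#'
#' @param dag a `bdmm_dag`.
#' @param x,y node names, distinct, not in `given`.
#' @param given character vector of conditioning nodes (default empty).
#' @return `TRUE` iff `x` and `y` are d-separated given `given`.
#' @export
#' @examples
#' chain <- dag(c("A", "B", "C"), list(B = "A", C = "B"))
#' d_separated(chain, "A", "C", "B")  # TRUE
#' d_separated(chain, "A", "C")      # FALSE
d_separated <- function(dag, x, y, given = character()) {
  stopifnot(x != y)
  check_nodes(dag, c(x, y, given))
  if (x %in% given || y %in% given) stop("conditioning set must exclude x, y")
  keep <- unique(unlist(lapply(c(x, y, given), ancestors_of, dag = dag)))
  # moralize the induced ancestral subgraph
  adj <- setNames(lapply(keep, function(.) character(0)), keep)
  link <- function(a, b) {
    adj[[a]] <<- union(adj[[a]], b)
    adj[[b]] <<- union(adj[[b]], a)
  }
  for (v in keep) {
    ps <- intersect(dag$parents[[v]], keep)
    for (p in ps) link(p, v)
    if (length(ps) > 1L) {
      cmb <- utils::combn(ps, 2L)
      for (k in seq_len(ncol(cmb))) link(cmb[1L, k], cmb[2L, k])
    }
  }
  # remove conditioning nodes, test reachability x -> y
  avoid <- given
  seen <- x
  frontier <- x
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)),
                   c(seen, avoid))
    if (y %in% nxt) return(FALSE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  TRUE
}

#' Structural-association feature
#'
#' True iff the two nodes are d-connected given the conditioning set. With
#' the default empty set this is marginal d-connection, the structural
#' feature whose model-averaged posterior is the BDMM structural
#' association.  Confounders such as sex and age are ordinary nodes of the
#' network rather than conditioned away; a non-empty `conditioning` is
#' provided for sensitivity analysis.
#'
#' @inheritParams d_separated
#' @param conditioning conditioning node set (default empty).
#' @return logical flag.
#' @export
association_feature <- function(dag, x, y, conditioning = character()) {
  !d_separated(dag, x, y, conditioning)
}

#' Serialize / deserialize a DAG as JSON (child -> parents)
#' @param dag a `bdmm_dag`.
#' @param path file path.
#' @return `write_dag_json` returns `path` invisibly; `read_dag_json` a
#'   `bdmm_dag`.
#' @export
write_dag_json <- function(dag, path) {
  jsonlite::write_json(list(nodes = dag$nodes, parents = dag$parents), path,
                       auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_dag_json
#' @export
read_dag_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  parents <- lapply(x$parents, as.character)
  dag(as.character(x$nodes), parents)
}

#' Write a DAG as an oriented edge-list TSV
#' @inheritParams write_dag_json
#' @export
write_dag_edgelist <- function(dag, path) {
  write.table(dag_edges(dag), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
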