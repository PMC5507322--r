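#' Hypergeometric gene-set overlap
#'
#' Upper-tail probability `P(X >= overlap)` of the hypergeometric
#' distribution: drawing `|A|` genes from a universe of `universe_size`
#' containing `|B|` successes.  Computed on the log scale via
#' [stats::phyper].  An empty set yields p = 1 with a flag.
#'
#' @param setA,setB character (or integer) vectors of gene ids, within the
#'   universe.
#' @param universe_size size of the gene universe.
#' @return list with `overlap`, `p`, `empty` flag.
#' @export
#' @examples
#' hypergeom_overlap(letters[1:4], letters[c(1:3, 5, 6)], 10)
hypergeom_overlap <- function(setA, setB, universe_size) {
  setA <- unique(setA); setB <- unique(setB)
  if (length(setA) > universe_size || length(setB) > universe_size)
    stop("set larger than universe")
  if (!length(setA) || !length(setB))
    return(list(overlap = 0L, p = 1, empty = TRUE))
  k <- length(intersect(setA, setB))
  # P(X >= k); phyper gives P(X <= q), so take the upper tail at k - 1
  logp <- phyper(k - 1L, length(setB), universe_size - length(setB),
                 length(setA), lower.tail = FALSE, log.p = TRUE)
  list(overlap = k, p = exp(logp), empty = FALSE)
}

#' Interactome-based separation score of two disease gene modules
#'
#' Network-module separation on the interactome:
#' `d_AB` averages, over every gene of A and of B, the shortest-path
#' distance to the nearest gene of the *other* set (genes in both sets
#' contribute 0); `d_AA` (and `d_BB`) average each gene's distance to the
#' nearest *distinct* member of its own set (0 for singleton sets).  The
#' separation score is `s_AB = d_AB - (d_AA + d_BB) / 2`; negative values
#' indicate topologically overlapping modules.  Genes absent from the
#' interactome are dropped (counted in the result); unreachable targets
#' are excluded from the means rather than treated as infinite.
#'
#' @param graph an [igraph::igraph] interactome (undirected, simple).
#' @param setA,setB gene-id vectors.
#' @return list with `d_AB`, `d_AA`, `d_BB`, `s_AB`, `n_dropped`; all
#'   distance fields `NA` when a set maps to nothing.
#' @export
separation_score <- function(graph, setA, setB) {
  vs <- igraph::V(graph)$name
  a <- unique(as.character(setA)); b <- unique(as.character(setB))
  dropped <- length(setdiff(a, vs)) + length(setdiff(b, vs))
  a <- intersect(a, vs); b <- intersect(b, vs)
  if (dropped)
    message("separation_score: ", dropped,
            " gene(s) absent from the interactome dropped")
  if (!length(a) || !length(b))
    return(list(d_AB = NA_real_, d_AA = NA_real_, d_BB = NA_real_,
                s_AB = NA_real_, n_dropped = dropped))
  dm <- igraph::distances(graph, v = unique(c(a, b)),
                          to = unique(c(a, b)), weights = NA)
  nearest_other <- function(from, to_set) {
    # min distance from each `from` gene to the other set (0 if member)
    vapply(from, function(g) {
      d <- dm[g, to_set]
      d <- d[is.finite(d)]
      if (!length(d)) NA_real_ else min(d)
    }, 1.0)
  }
  nearest_same <- function(set) {
    if (length(set) == 1L) return(0)
    v <- vapply(set, function(g) {
      d <- dm[g, setdiff(set, g)]
      d <- d[is.finite(d)]
      if (!length(d)) NA_real_ else min(d)
    }, 1.0)
    mean(v, na.rm = TRUE)
  }
  dab <- mean(c(nearest_other(a, b), nearest_other(b, a)), na.rm = TRUE)
  daa <- nearest_same(a)
  dbb <- nearest_same(b)
  list(d_AB = dab, d_AA = daa, d_BB = dbb,
       s_AB = dab - (daa + dbb) / 2, n_dropped = dropped)
}

#' Molecular scores for every disease pair
#'
#' Combines [hypergeom_overlap()] and [separation_score()] for all pairs
#' of diseases present in a gene-disease table.
#'
#' @param gene_table data.frame with columns `disease_id`, `gene_id`.
#' @param interactome an [igraph::igraph] on gene ids.
#' @param universe `"genes"` (union of genes in the table, default) or
#'   `"interactome"` (node count of the interactome).
#' @return data.frame, one row per unordered disease pair, with overlap
#'   count, hypergeometric p, the three mean distances and `s_AB`.
#' @export
molecular_table <- function(gene_table, interactome,
                            universe = c("genes", "interactome")) {
  universe <- match.arg(universe)
  stopifnot(all(c("disease_id", "gene_id") %in% names(gene_table)))
  sets <- split(as.character(gene_table$gene_id), gene_table$disease_id)
  N <- if (universe == "genes") length(unique(gene_table$gene_id))
  else igraph::vcount(interactome)
  ds <- sort(names(sets))
  pairs <- utils::combn(ds, 2L)
  out <- data.frame(var1 = pairs[1L, ], var2 = pairs[2L, ],
                    overlap = NA_integer_, p_overlap = NA_real_,
                    d_AB = NA_real_, d_AA = NA_real_, d_BB = NA_real_,
                    s_AB = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    A <- sets[[pairs[1L, k]]]; B <- sets[[pairs[2L, k]]]
    hg <- hypergeom_overlap(A, B, N)
    sp <- suppressMessages(separation_score(interactome, A, B))
    out$overlap[k] <- hg$overlap
    out$p_overlap[k] <- hg$p
    out$d_AB[k] <- sp$d_AB; out$d_AA[k] <- sp$d_AA; out$d_BB[k] <- sp$d_BB
    out$s_AB[k] <- sp$s_AB
  }
  out
}

#' Cross-level comparison of epidemiological and molecular relations
#'
#' Per shared disease pair, the four edge-type flags of the two-level
#' view: pairwise-epidemiological (RR 95% CI excluding 1), pairwise-
#' molecular (overlap p < 0.05), systems-molecular (negative separation
#' score) and systems-epidemiological (BDMM posterior above the map
#' cut-off).  Agreement between flag pairs is summarised by the Jaccard
#' index.
#'
#' @param pairwise a [pairwise_table()] (for RR confidence intervals).
#' @param posteriors a `bdmm_posteriors`.
#' @param molecular a [molecular_table()].
#' @param pr_cutoff map-membership posterior cut-off (default 0.05).
#' @return data.frame of flags per pair with a `jaccard` attribute (named
#'   matrix of pairwise flag agreements).
#' @export
cross_level_table <- function(pairwise, posteriors, molecular,
                              pr_cutoff = 0.05) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  kp <- key(pairwise$var1, pairwise$var2)
  km <- key(molecular$var1, molecular$var2)
  shared <- intersect(kp, km)
  shared <- shared[vapply(strsplit(shared, " "), function(v)
    all(v %in% posteriors$variables), TRUE)]
  if (!length(shared)) stop("no shared disease pairs across levels")
  ip <- match(shared, kp); im <- match(shared, km)
  v1 <- pairwise$var1[ip]; v2 <- pairwise$var2[ip]
  flags <- data.frame(
    var1 = v1, var2 = v2,
    rr_ci_excludes_1 = pairwise$rr_lo[ip] > 1 | pairwise$rr_hi[ip] < 1,
    overlap_significant = molecular$p_overlap[im] < 0.05,
    separation_negative = molecular$s_AB[im] < 0,
    bdmm_member = posteriors$edge[cbind(v1, v2)] > pr_cutoff,
    stringsAsFactors = FALSE)
  fl <- flags[, 3:6]
  jac <- matrix(NA_real_, 4L, 4L, dimnames = list(names(fl), names(fl)))
  for (i in 1:4) for (j in 1:4) {
    x <- fl[[i]] & !is.na(fl[[i]]); y <- fl[[j]] & !is.na(fl[[j]])
    u <- sum(x | y)
    jac[i, j] <- if (u == 0) NA_real_ else sum(x & y) / u
  }
  attr(flags, "jaccard") <- jac
  flags
}

#' Read a gene-disease association table
#'
#' Two-column delimited text: `disease_id`, `gene_id` (header required).
#'
#' @param path input path.
#' @return data.frame with character columns.
#' @export
read_gene_disease <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("disease_id", "gene_id") %in% names(df)))
    stop("expected columns disease_id, gene_id in ", path)
  df$disease_id <- as.character(df$disease_id)
  df$gene_id <- as.character(df$gene_id)
  df
}

#' Read an interactome edge list
#'
#' Two-column delimited text of undirected gene-gene links; self-loops and
#' duplicate edges are removed.
#'
#' @param path input path.
#' @return an [igraph::igraph].
#' @export
read_interactome <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected two columns in ", path)
  g <- igraph::graph_from_data_frame(df[, 1:2], directed = FALSE)
  igraph::simplify(g)
}
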