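#' 2x2 contingency table for a disease pair
#'
#' Counts the four joint outcomes: `a` both present, `b` first only,
#' `c` second only, `d` both absent.
#'
#' @param cohort a `bdmm_cohort` (or data.frame of 0/1 columns).
#' @param disease_i,disease_j column names.
#' @return named integer vector `c(a, b, c, d)`.
#' @export
contingency <- function(cohort, disease_i, disease_j) {
  df <- if (inherits(cohort, "bdmm_cohort")) cohort$data else cohort
  if (!disease_i %in% names(df)) stop("unknown column: ", disease_i)
  if (!disease_j %in% names(df)) stop("unknown column: ", disease_j)
  x <- df[[disease_i]]; y <- df[[disease_j]]
  stopifnot(all(x %in% 0:1), all(y %in% 0:1))
  c(a = sum(x == 1L & y == 1L), b = sum(x == 1L & y == 0L),
    c = sum(x == 0L & y == 1L), d = sum(x == 0L & y == 0L))
}

tab_margins <- function(t) {
  c(r1 = t[["a"]] + t[["b"]], r2 = t[["c"]] + t[["d"]],
    c1 = t[["a"]] + t[["c"]], c2 = t[["b"]] + t[["d"]])
}

#' Chi-squared test with Yates' continuity correction
#'
#' `X^2 = N (|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))`, floored at zero
#' when the correction exceeds `|ad - bc|`; p-value from the chi-squared
#' distribution with 1 df.  Tables with a zero margin are degenerate:
#' statistic 0, p 1, `degenerate` flag set.
#'
#' @param t a contingency vector from [contingency()].
#' @return list with `statistic`, `p_value`, `degenerate`.
#' @export
chi2_yates <- function(t) {
  N <- sum(t)
  stopifnot(N > 0)
  m <- tab_margins(t)
  if (any(m == 0))
    return(list(statistic = 0, p_value = 1, degenerate = TRUE))
  dlt <- abs(t[["a"]] * t[["d"]] - t[["b"]] * t[["c"]])
  stat <- if (dlt < N / 2) 0 else N * (dlt - N / 2)^2 / prod(m)
  list(statistic = unname(stat),
       p_value = unname(pchisq(stat, df = 1, lower.tail = FALSE)),
       degenerate = FALSE)
}

#' Bonferroni significance flags
#'
#' @param p_values numeric vector of p-values (one family).
#' @param alpha family-wise level (default 0.05).
#' @param m family size; defaults to `length(p_values)`.
#' @return logical vector, `p < alpha / m`.
#' @export
bonferroni_adjust <- function(p_values, alpha = 0.05,
                              m = length(p_values)) {
  if (length(p_values) == 0L) return(logical(0))
  p_values < alpha / m
}

haldane <- function(t) {
  if (any(t == 0)) list(t = t + 0.5, corrected = TRUE)
  else list(t = t, corrected = FALSE)
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' `OR = ad / bc`; CI `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.
#' Any zero cell triggers the Haldane-Anscombe +0.5 correction of all four
#' cells, flagged in the result.
#'
#' @param t a contingency vector.
#' @return list with `or`, `ci` (length-2), `corrected`.
#' @export
odds_ratio_ci <- function(t) {
  h <- haldane(t)
  tt <- h$t
  or <- (tt[["a"]] * tt[["d"]]) / (tt[["b"]] * tt[["c"]])
  se <- sqrt(sum(1 / tt))
  list(or = unname(or),
       ci = unname(exp(log(or) + c(-1, 1) * 1.96 * se)),
       corrected = h$corrected)
}

#' Risk ratio with log-scale 95% confidence interval
#'
#' `RR = [a/(a+b)] / [c/(c+d)]`; `se = sqrt(b/(a(a+b)) + d/(c(c+d)))`.
#' Zero cells handled as in [odds_ratio_ci()].
#'
#' @param t a contingency vector.
#' @return list with `rr`, `ci`, `corrected`.
#' @export
risk_ratio_ci <- function(t) {
  h <- haldane(t)
  tt <- h$t
  r1 <- tt[["a"]] + tt[["b"]]; r2 <- tt[["c"]] + tt[["d"]]
  rr <- (tt[["a"]] / r1) / (tt[["c"]] / r2)
  se <- sqrt(tt[["b"]] / (tt[["a"]] * r1) + tt[["d"]] / (tt[["c"]] * r2))
  list(rr = unname(rr),
       ci = unname(exp(log(rr) + c(-1, 1) * 1.96 * se)),
       corrected = h$corrected)
}

#' Phi coefficient (Pearson correlation of two binaries)
#'
#' `phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))`; `NA` when a margin is
#' zero.
#'
#' @param t a contingency vector.
#' @return numeric in \[-1, 1\] or `NA`.
#' @export
phi_coefficient <- function(t) {
  m <- tab_margins(t)
  if (any(m == 0)) return(NA_real_)
  unname((t[["a"]] * t[["d"]] - t[["b"]] * t[["c"]]) / sqrt(prod(m)))
}

#' Transform chi-squared p-values to the parametric-association scale
#'
#' Maps p-values to \[0, 1\] with the scale inverted so that stronger
#' evidence scores higher: `T(p) = -log10(p) / (ld_star + 1)` where
#' `ld_star` is the maximum of `-log10(p)` over the strictly positive
#' p-values of the batch; `T(0) = 1`.  Scores are only comparable within
#' one batch.
#'
#' @param p_values numeric vector in \[0, 1\] (one batch).
#' @return numeric vector of scores in \[0, 1\]; attribute `ld_star`
#'   carries the batch maximum.
#' @export
transform_parametric_association <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  pos <- p_values[p_values > 0]
  ld_star <- if (length(pos)) max(-log10(pos)) else NA_real_
  out <- ifelse(p_values == 0, 1, -log10(p_values) / (ld_star + 1))
  attr(out, "ld_star") <- ld_star
  out
}

transform_ratio <- function(values, lower = 0.01, upper = 100) {
  in_range <- is.finite(values) & values > lower & values < upper
  star <- if (any(in_range)) max(pmax(values[in_range], 1 / values[in_range]))
  else NA_real_
  score <- rep(NA_real_, length(values))
  up <- in_range & values >= 1
  dn <- in_range & values < 1
  score[up] <- values[up] / star
  score[dn] <- 1 / (values[dn] * star)
  list(score = score, ignored = !in_range, star = star)
}

#' Transform odds ratios to the \[0, 1\] scale
#'
#' Values outside (0.01, 100) are ignored.  With `OR_star` the batch
#' maximum of `max(OR, 1/OR)` over in-range values: `T(OR) = OR / OR_star`
#' for `OR >= 1` and `T(OR) = 1 / (OR * OR_star)` for `OR < 1`, so that
#' `T(x) = T(1/x)` and the batch maximum is exactly 1.
#'
#' @param or_values numeric vector of odds ratios (one batch).
#' @return list with `score` (`NA` where ignored), `ignored` flags and the
#'   batch `star`.
#' @export
transform_or <- function(or_values) transform_ratio(or_values)

#' Transform risk ratios to the \[0, 1\] scale
#'
#' Identical to [transform_or()] with RR in place of OR.
#'
#' @param rr_values numeric vector of risk ratios (one batch).
#' @return list with `score`, `ignored`, `star`.
#' @export
transform_rr <- function(rr_values) transform_ratio(rr_values)

#' All pairwise comorbidity statistics
#'
#' Computes, for every unordered disease pair, the 2x2 counts, the
#' Yates-corrected chi-squared test, Bonferroni flags (family = number of
#' disease-disease pairs tested; sex/age never enter), OR and RR with 95%
#' CIs (Haldane-corrected where needed), the phi coefficient, and the
#' three batch transforms.
#'
#' @param cohort a `bdmm_cohort`.
#' @param diseases columns to test (default: all disease columns).
#' @param alpha family-wise level for the Bonferroni flags.
#' @return data.frame, one row per pair, with attributes `ld_star`,
#'   `or_star`, `rr_star`, `m` (family size).
#' @export
pairwise_table <- function(cohort, diseases = cohort_diseases(cohort),
                           alpha = 0.05) {
  stopifnot(length(diseases) >= 2L)
  pairs <- utils::combn(diseases, 2L)
  np <- ncol(pairs)
  res <- data.frame(var1 = pairs[1L, ], var2 = pairs[2L, ],
                    a = NA_integer_, b = NA_integer_, c = NA_integer_,
                    d = NA_integer_, chi2_stat = NA_real_,
                    chi2_p = NA_real_, or = NA_real_, or_lo = NA_real_,
                    or_hi = NA_real_, rr = NA_real_, rr_lo = NA_real_,
                    rr_hi = NA_real_, phi = NA_real_,
                    corrected = NA, stringsAsFactors = FALSE)
  for (k in seq_len(np)) {
    t <- contingency(cohort, pairs[1L, k], pairs[2L, k])
    chi <- chi2_yates(t)
    or <- odds_ratio_ci(t)
    rr <- risk_ratio_ci(t)
    res[k, c("a", "b", "c", "d")] <- as.list(t)
    res$chi2_stat[k] <- chi$statistic
    res$chi2_p[k] <- chi$p_value
    res$or[k] <- or$or; res$or_lo[k] <- or$ci[1]; res$or_hi[k] <- or$ci[2]
    res$rr[k] <- rr$rr; res$rr_lo[k] <- rr$ci[1]; res$rr_hi[k] <- rr$ci[2]
    res$phi[k] <- phi_coefficient(t)
    res$corrected[k] <- or$corrected
  }
  res$bonferroni <- bonferroni_adjust(res$chi2_p, alpha = alpha)
  tp <- transform_parametric_association(res$chi2_p)
  res$t_chi2 <- as.numeric(tp)
  tor <- transform_or(res$or)
  trr <- transform_rr(res$rr)
  res$t_or <- tor$score
  res$t_rr <- trr$score
  attr(res, "ld_star") <- attr(tp, "ld_star")
  attr(res, "or_star") <- tor$star
  attr(res, "rr_star") <- trr$star
  attr(res, "m") <- np
  res
}

#' Logistic regression on a target disease
#'
#' Maximum-likelihood fit (no interactions) of
#' `logit P(target = 1) = beta0 + sum_j beta_j x_j`, the standard
#' epidemiological adjustment tool.  Constant predictors are dropped with
#' a warning; (quasi-)separation is detected from the glm warnings and
#' flagged.  Convergence: relative deviance change below 1e-8 or 100
#' iterations.
#'
#' @param cohort a `bdmm_cohort`.
#' @param target_disease binary outcome column.
#' @param predictors predictor columns (default: all other diseases plus
#'   sex and age).
#' @return data.frame with one row per kept predictor (`term`, `estimate`,
#'   `std_error`, `p_value`); attribute `separation` flags a suspect fit,
#'   attribute `dropped` lists removed predictors.
#' @export
logistic_fit <- function(cohort, target_disease,
                         predictors = setdiff(names(cohort$data),
                                              target_disease)) {
  df <- cohort$data
  if (!target_disease %in% names(df))
    stop("unknown target: ", target_disease)
  stopifnot(!target_disease %in% predictors)
  keep <- predictors[vapply(df[predictors],
                            function(col) length(unique(col)) > 1L, TRUE)]
  dropped <- setdiff(predictors, keep)
  if (length(dropped))
    warning("dropping constant predictor(s): ",
            paste(dropped, collapse = ", "))
  if (!length(keep)) stop("no usable predictors")
  fm <- stats::as.formula(paste(target_disease, "~",
                                paste(keep, collapse = " + ")))
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(fm, data = df, family = binomial(),
        control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  # diverging coefficients are the practical footprint of separation even
  # when glm stops before the numeric-0/1 warning fires
  if (any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)) separation <- TRUE
  if (separation)
    warning("possible separation: fitted probabilities of 0 or 1 occurred")
  sm <- summary(fit)$coefficients
  out <- data.frame(term = rownames(sm), estimate = sm[, 1],
                    std_error = sm[, 2], p_value = sm[, 4],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "separation") <- separation
  attr(out, "dropped") <- dropped
  out
}

#' Ward clustering of a p-value matrix
#'
#' Agglomerative Ward linkage with the p-values used directly as
#' dissimilarities (no squaring), reproducing the "p-values as distances"
#' hierarchical view of the diseasome.
#'
#' @param p_value_matrix symmetric matrix with zero diagonal.
#' @return an [stats::hclust] object.
#' @export
ward_clustering <- function(p_value_matrix) {
  m <- as.matrix(p_value_matrix)
  if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m), tolerance = 1e-12,
                                              check.attributes = FALSE)))
    stop("p-value matrix must be symmetric")
  if (any(diag(m) != 0)) stop("diagonal must be zero")
  hclust(as.dist(m), method = "ward.D")
}

#' Newick string for a dendrogram
#'
#' @param hc an [stats::hclust] object.
#' @return single Newick-format string with merge heights as branch
#'   lengths.
#' @export
ward_newick <- function(hc) {
  lab <- hc$labels
  if (is.null(lab)) lab <- as.character(seq_len(length(hc$order)))
  build <- function(i, parent_h) {
    if (i < 0) return(paste0(lab[-i], ":", format(parent_h, digits = 10)))
    h <- hc$height[i]
    paste0("(", build(hc$merge[i, 1], h), ",", build(hc$merge[i, 2], h),
           "):", format(parent_h - h, digits = 10))
  }
  n <- nrow(hc$merge)
  h <- hc$height[n]
  paste0("(", build(hc$merge[n, 1], h), ",", build(hc$merge[n, 2], h), ");")
}

#' Write a pairwise table as TSV
#'
#' Long-format export of [pairwise_table()]; batch transform context is
#' echoed as `#`-prefixed header lines because transformed scores are not
#' comparable across batches.
#'
#' @param pw a [pairwise_table()] result.
#' @param path output path.
#' @export
write_pairwise_tsv <- function(pw, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ld_star=%.10g or_star=%.10g rr_star=%.10g m=%d",
                     attr(pw, "ld_star"), attr(pw, "or_star"),
                     attr(pw, "rr_star"), attr(pw, "m")), con)
  write.table(pw, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
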