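#' Convert a count matrix to presence/absence
#'
#' @param counts Non-negative numeric matrix (samples x ASVs).
#' @return Binary matrix of the same shape: 1 where `counts >= 1`.
#' @export
to_presence_absence <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0, na.rm = TRUE))
  out <- (counts >= 1) + 0L
  dimnames(out) <- dimnames(counts)
  out
}

#' Group-conditional occurrence frequencies for one ASV
#'
#' The association statistic is, per habitat group, the fraction of that
#' group's samples in which the ASV occurs. The preferred group is the one
#' with the larger frequency; exact ties are flagged.
#'
#' @param presence Binary vector over samples.
#' @param groups Factor or character of sample habitat labels (two levels,
#'   both non-empty).
#' @return List: `stat` (named per-group frequencies), `preferred`,
#'   `statistic` (the larger frequency), `tie`.
#' @export
association_statistic <- function(presence, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) {
    stop("both habitat groups must be non-empty", call. = FALSE)
  }
  stat <- vapply(levels(groups), function(g) {
    mean(presence[groups == g])
  }, numeric(1))
  tie <- length(unique(stat)) == 1L
  list(stat = stat,
       preferred = names(stat)[which.max(stat)],
       statistic = max(stat),
       tie = tie)
}

# all distinct two-group labelings of n samples with n1 in group 1,
# as an n x N logical matrix (TRUE = group 1)
exhaustive_labelings <- function(n, n1) {
  combs <- utils::combn(n, n1)
  G <- matrix(FALSE, n, ncol(combs))
  for (j in seq_len(ncol(combs))) G[combs[, j], j] <- TRUE
  G
}

#' Permutation indicator analysis of habitat preference
#'
#' For every ASV, computes the group-conditional occurrence frequencies on
#' presence/absence data and tests the larger one against a label-permutation
#' null: sample habitat labels are permuted `n_perm` times (one shared
#' permutation stream across ASVs, so joint summaries keep their cross-ASV
#' correlation), the max-group statistic is recomputed, and
#' `p = (1 + #\{permuted >= observed\}) / (1 + n_perm)`. When the number of
#' distinct labelings does not exceed `n_perm`, the null is enumerated
#' exhaustively instead and `p` is the exact tail proportion. P-values are
#' Sidak-corrected for the number of habitat groups. ASVs absent from every
#' sample are excluded from testing (`p = 1`, flagged).
#'
#' @param counts Count (or presence) matrix, samples x ASVs.
#' @param groups Habitat label per sample (two levels).
#' @param n_perm Number of label permutations (default 9999).
#' @param seed Integer seed for the permutation stream.
#' @return data.frame of class `indicator_results`: per ASV the two group
#'   frequencies, preferred group, statistic, tie flag, prevalence, `p_perm`,
#'   `p_sidak`, `n_perm` and `method` (`"sampled"` or `"exhaustive"`).
#' @export
indicator_analysis <- function(counts, groups, n_perm = 9999, seed = 1L) {
  stopifnot(is.matrix(counts), n_perm >= 1)
  groups <- as.factor(groups)
  if (length(groups) != nrow(counts)) {
    stop("`groups` must label every row of `counts`", call. = FALSE)
  }
  if (nlevels(droplevels(groups)) != 2) {
    stop("indicator analysis requires exactly two habitat groups", call. = FALSE)
  }
  lv <- levels(droplevels(groups))
  pa <- to_presence_absence(counts)
  n <- nrow(pa)
  g1 <- groups == lv[1]
  n1 <- sum(g1); n2 <- n - n1

  f1 <- colSums(pa[g1, , drop = FALSE]) / n1
  f2 <- colSums(pa[!g1, , drop = FALSE]) / n2
  obs <- pmax(f1, f2)
  prevalence <- colMeans(pa)

  n_distinct <- choose(n, n1)
  exhaustive <- is.finite(n_distinct) && n_distinct <= n_perm
  if (exhaustive) {
    G <- exhaustive_labelings(n, n1)
    message(sprintf(
      "indicator_analysis: %d distinct labelings <= %d permutations; enumerating exhaustively",
      ncol(G), n_perm))
  } else {
    G <- with_seed(seed, {
      replicate(n_perm, {
        v <- logical(n)
        v[sample.int(n, n1)] <- TRUE
        v
      })
    })
  }
  # permuted frequencies via one matrix product per group
  P1 <- crossprod(pa, G) / n1           # ASVs x B occurrence freq in group 1
  P2 <- crossprod(pa, !G) / n2
  perm_max <- pmax(P1, P2)
  ge <- rowSums(perm_max >= matrix(obs, nrow = length(obs),
                                   ncol = ncol(perm_max)))
  p_perm <- if (exhaustive) ge / ncol(G) else (1 + ge) / (1 + ncol(G))

  constant <- prevalence == 0
  p_perm[constant] <- 1

  res <- data.frame(
    asv_id = colnames(pa) %||% paste0("V", seq_along(obs)),
    stringsAsFactors = FALSE)
  res[[paste0("stat_", lv[1])]] <- unname(f1)
  res[[paste0("stat_", lv[2])]] <- unname(f2)
  res$preferred_group <- ifelse(f1 > f2, lv[1], ifelse(f2 > f1, lv[2], "tie"))
  res$statistic <- unname(obs)
  res$tie <- f1 == f2
  res$prevalence <- unname(prevalence)
  res$p_perm <- unname(p_perm)
  res$p_sidak <- sidak_correct(res$p_perm, k = 2L)
  res$n_perm <- if (exhaustive) ncol(G) else n_perm
  res$method <- if (exhaustive) "exhaustive" else "sampled"
  res$tested <- !constant
  class(res) <- c("indicator_results", class(res))
  res
}

#' Sidak multiple-testing correction
#'
#' `p' = 1 - (1 - p)^k`, clipped to `[0, 1]`. Always at least the raw
#' p-value and never above the Bonferroni bound `k * p`.
#'
#' @param p Raw p-value(s) in `[0, 1]`.
#' @param k Number of hypotheses (>= 1).
#' @return Corrected p-value(s).
#' @export
sidak_correct <- function(p, k) {
  stopifnot(all(p >= 0 & p <= 1), k >= 1)
  pmin(1, pmax(0, 1 - (1 - p)^k))
}

#' Call significant indicator ASVs
#'
#' Significance is `p_sidak < alpha`. A separate reporting filter on
#' prevalence (e.g. `min_prevalence = 0.20` to display only ASVs present in
#' more than 20% of samples) restricts the returned rows without altering
#' the significance call.
#'
#' @param results An `indicator_results` data.frame.
#' @param alpha Significance level (default 0.05).
#' @param min_prevalence Display filter: keep ASVs with prevalence strictly
#'   above this (default 0, no filtering).
#' @return The significant (and displayed) rows, with a `significant`
#'   column.
#' @export
call_indicators <- function(results, alpha = 0.05, min_prevalence = 0) {
  results$significant <- results$p_sidak < alpha & results$tested
  out <- results[results$significant & results$prevalence > min_prevalence, ,
                 drop = FALSE]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' @export
print.indicator_results <- function(x, ...) {
  sig <- sum(x$p_sidak < 0.05 & x$tested)
  cat(sprintf("Indicator analysis: %d ASVs, %d permutations (%s), %d significant at Sidak p < 0.05\n",
              nrow(x), x$n_perm[1] %||% NA, x$method[1] %||% "?", sig))
  invisible(x)
}
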