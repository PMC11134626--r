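#' Rank imaging features by projection weight
#'
#' The enriched value of a participant is a weighted sum of their original
#' biomarkers, so the total absolute weight that row `q` of the projections
#' receives across the cohort, `sum_i ||e_q' W_i||_1`, measures how much
#' feature `q` contributes to the learned representation and can be read as
#' disease relevance.
#'
#' @param W list of `d x r1` projection matrices (e.g. `fit$state$W`).
#' @param modality_slices optional named list tagging each feature row with
#'   its modality.
#' @return data.frame with columns `feature`, `modality`, `score`, `rank`
#'   (descending score, ties broken by feature index).
#' @export
imaging_importance <- function(W, modality_slices = NULL) {
  stopifnot(length(W) >= 1L)
  score <- Reduce(`+`, lapply(W, function(Wi) rowSums(abs(Wi))))
  d <- length(score)
  modality <- rep(NA_character_, d)
  if (!is.null(modality_slices)) {
    for (nm in names(modality_slices)) modality[modality_slices[[nm]]] <- nm
  }
  out <- data.frame(feature = seq_len(d), modality = modality, score = score)
  out$rank <- rank(-out$score, ties.method = "first")
  out[order(out$rank), , drop = FALSE]
}

#' Rank SNPs and SNP groups by loading weight
#'
#' Per-SNP score is the L1 norm of that SNP's row of the genetic loading
#' matrix `H0`; group score is the mean (optionally the sum) of its members'
#' scores, reported with the within-group standard deviation.
#'
#' @param H0 `d_SNP x r2` loading matrix (e.g. `fit$state$H0`).
#' @param groups list of integer vectors partitioning `1:nrow(H0)`.
#' @param group_aggregate `"mean"` (default, so large groups do not dominate)
#'   or `"sum"`.
#' @return list with data.frames `snp` (`snp`, `group`, `score`, `rank`) and
#'   `group` (`group`, `size`, `score`, `sd`, `rank`).
#' @export
snp_importance <- function(H0, groups, group_aggregate = c("mean", "sum")) {
  group_aggregate <- match.arg(group_aggregate)
  idx <- unlist(groups, use.names = FALSE)
  stopifnot(setequal(idx, seq_len(nrow(H0))), !anyDuplicated(idx))
  score <- rowSums(abs(as.matrix(H0)))
  gid <- integer(nrow(H0))
  for (k in seq_along(groups)) gid[groups[[k]]] <- k
  snp <- data.frame(snp = seq_along(score), group = gid, score = score)
  snp$rank <- rank(-snp$score, ties.method = "first")

  agg <- vapply(groups, function(g) {
    s <- score[g]
    c(if (group_aggregate == "mean") mean(s) else sum(s),
      if (length(s) > 1) stats::sd(s) else 0)
  }, numeric(2))
  grp <- data.frame(group = seq_along(groups), size = lengths(groups),
                    score = agg[1, ], sd = agg[2, ])
  grp$rank <- rank(-grp$score, ties.method = "first")
  list(snp = snp[order(snp$rank), , drop = FALSE],
       group = grp[order(grp$rank), , drop = FALSE])
}
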