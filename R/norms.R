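#' Row-wise L2,1 norm
#'
#' Sum of the Euclidean norms of the rows of `M`.  This is the robust loss
#' used throughout the model: grouping a residual's entries by row before
#' taking the square root caps the influence of any single large row.
#'
#' @param M numeric matrix (an empty matrix gives 0).
#' @return nonnegative scalar.
#' @export
l21_norm <- function(M) {
  M <- as.matrix(M)
  if (length(M) == 0L) return(0)
  sum(sqrt(rowSums(M^2)))
}

#' Group L2 norm of SNP loadings
#'
#' Sum over row groups of each block's Frobenius norm; drives entire groups
#' of loadings to zero jointly.
#'
#' @param H0 numeric matrix (`d_SNP` rows).
#' @param groups list of integer vectors partitioning `1:nrow(H0)`.
#' @return nonnegative scalar.
#' @export
group_l2_norm <- function(H0, groups) {
  H0 <- as.matrix(H0)
  idx <- unlist(groups, use.names = FALSE)
  if (length(idx) != nrow(H0) || anyDuplicated(idx) ||
      !setequal(idx, seq_len(nrow(H0)))) {
    stop("groups must be a disjoint partition of the rows of H0")
  }
  sum(vapply(groups,
             function(g) sqrt(sum(H0[g, , drop = FALSE]^2)),
             numeric(1)))
}

#' Trace norm (sum of singular values)
#'
#' @param M numeric matrix.
#' @return nonnegative scalar.
#' @export
trace_norm <- function(M) {
  M <- as.matrix(M)
  if (length(M) == 0L) return(0)
  sum(svd(M, nu = 0, nv = 0)$d)
}

#' Unfold a stack of projection matrices
#'
#' Mode 1 concatenates the matrices horizontally (`d x r1*n`); mode 2
#' concatenates their transposes (`r1 x d*n`).  These are the two matrices
#' whose trace norms couple all participants' projections.
#'
#' @param W list of `n` numeric matrices of identical shape `d x r1`.
#' @param mode 1 or 2.
#' @return the unfolded matrix.
#' @export
unfold <- function(W, mode) {
  stopifnot(length(W) >= 1L, mode %in% c(1L, 2L))
  dims <- vapply(W, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all W_i must share the same shape")
  }
  if (mode == 1L) do.call(cbind, W) else do.call(cbind, lapply(W, t))
}

#' Refold an unfolded projection stack back into a list
#'
#' Inverse of [unfold()]: `refold(unfold(W, mode), d, r1, mode)` returns `W`.
#'
#' @param M the unfolded matrix.
#' @param d,r1 per-matrix dimensions.
#' @param mode 1 or 2 (the mode used to unfold).
#' @return list of `d x r1` matrices.
#' @export
refold <- function(M, d, r1, mode) {
  if (mode == 1L) {
    n <- ncol(M) / r1
    lapply(seq_len(n), function(i) M[, ((i - 1) * r1 + 1):(i * r1), drop = FALSE])
  } else {
    n <- ncol(M) / d
    lapply(seq_len(n), function(i) t(M[, ((i - 1) * d + 1):(i * d), drop = FALSE]))
  }
}

#' Enrich every participant's last record
#'
#' Applies each participant's projection to their most recent visit:
#' column `i` of the result is `t(W_i) %*% x_i`, the fixed-length enriched
#' representation.
#'
#' @param cohort a `longitudinal_cohort` (or any list with `last_records`).
#' @param W list of `d x r1` projection matrices, one per participant.
#' @return `r1 x n` matrix `Z`.
#' @export
enrich_all <- function(cohort, W) {
  X <- cohort$last_records
  stopifnot(length(W) == ncol(X), nrow(W[[1]]) == nrow(X))
  Z <- vapply(seq_along(W), function(i) drop(crossprod(W[[i]], X[, i])),
              numeric(ncol(W[[1]])))
  matrix(Z, ncol = ncol(X))
}
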