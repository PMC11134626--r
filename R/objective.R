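# Residual matrices of the five robust data-fit terms, reused by the
# objective evaluators and by the reweighting step.
residual_matrices <- function(state, cohort) {
  Z <- enrich_all(cohort, state$W)
  list(
    label = crossprod(state$U, state$G1) - state$Fmat,           # c x n
    pca = lapply(seq_along(state$W), function(i) {
      Xi <- cohort$histories[[i]]; Wi <- state$W[[i]]
      Xi - Wi %*% crossprod(Wi, Xi)                              # d x n_i
    }),
    imaging = Z - state$H1 %*% state$G1,                         # r1 x n
    snp = cohort$snp_matrix - state$H0 %*% state$G0,             # d_SNP x n
    align = state$G1 - state$G0,                                 # r2 x n
    Z = Z
  )
}

#' Evaluate every term of the enrichment objective
#'
#' Computes the non-smooth objective: the robust label-regression loss plus
#' the gamma-weighted robust PCA fit, imaging factorization, SNP
#' factorization, latent alignment, group-sparsity, trace-norm and L1
#' regularizers.
#'
#' @param state a model state (see [init_state()]).
#' @param cohort a `longitudinal_cohort`.
#' @param hp an [hyperparams()] object.
#' @return list of class `term_values` with one field per term plus `total`.
#' @export
eval_objective <- function(state, cohort, hp) {
  res <- residual_matrices(state, cohort)
  g <- hp$gamma
  terms <- list(
    label_fit = l21_norm(-res$label),       # ||F - t(U) G1||_2,1
    pca_fit = sum(vapply(res$pca, l21_norm, numeric(1))),
    imaging_factor = l21_norm(res$imaging),
    snp_factor = l21_norm(res$snp),
    align = l21_norm(res$align),
    group_reg = group_l2_norm(state$H0, cohort$snp_groups),
    trace_reg = trace_norm(unfold(state$W, 1L)) + trace_norm(unfold(state$W, 2L)),
    sparsity_reg = sum(abs(state$U))
  )
  terms$total <- terms$label_fit + g[1] * terms$pca_fit +
    g[2] * terms$imaging_factor + g[3] * terms$snp_factor +
    g[4] * terms$align + g[5] * terms$group_reg +
    g[6] * terms$trace_reg + g[7] * terms$sparsity_reg
  class(terms) <- "term_values"
  terms
}

#' @export
print.term_values <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("  %-15s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

# row weights 1 / (2 sqrt(||row||^2 + delta)) of the reweighted surrogate
row_weights <- function(R, delta) 1 / (2 * sqrt(rowSums(R^2) + delta))

# 0.5 * (S + delta I)^(-1/2) for symmetric psd S, by eigendecomposition with
# symmetrization first (floating-point hygiene); eigenvalues are floored at
# zero before the delta shift.
inv_sqrt_half <- function(S, delta) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0) + delta
  0.5 * e$vectors %*% (t(e$vectors) / sqrt(vals))
}

#' Build the reweighting matrices of the smoothed surrogate
#'
#' Each non-smooth norm of the objective is majorized by a weighted
#' quadratic whose weights come from the current iterate: row residual
#' norms give diagonal weights `1 / (2 sqrt(||r_j||^2 + delta))`, the group
#' regularizer gives one scalar per SNP group, and the two trace norms give
#' the matrices `0.5 (W_unfold W_unfold' + delta I)^(-1/2)`.
#'
#' @param state a model state.
#' @param cohort a `longitudinal_cohort`.
#' @param delta smoothing constant (> 0 keeps every weight finite).
#' @return list of class `weight_matrices` with fields `d1`, `d2` (list),
#'   `d3`, `d4`, `d5`, `d6_blocks` (K scalars), `D7`, `D8`, `d9` (list of
#'   `c` vectors).
#' @export
reweight <- function(state, cohort, delta) {
  stopifnot(delta >= 0)
  res <- residual_matrices(state, cohort)
  W1 <- unfold(state$W, 1L)
  W2 <- unfold(state$W, 2L)
  w <- list(
    d1 = row_weights(res$label, delta),
    d2 = lapply(res$pca, row_weights, delta = delta),
    d3 = row_weights(res$imaging, delta),
    d4 = row_weights(res$snp, delta),
    d5 = row_weights(res$align, delta),
    d6_blocks = vapply(cohort$snp_groups, function(g) {
      0.5 / sqrt(sum(state$H0[g, , drop = FALSE]^2) + delta)
    }, numeric(1)),
    D7 = inv_sqrt_half(tcrossprod(W1), delta),
    D8 = inv_sqrt_half(tcrossprod(W2), delta),
    d9 = lapply(seq_len(ncol(state$U)), function(q) {
      1 / (2 * sqrt(state$U[, q]^2 + delta))
    })
  )
  class(w) <- "weight_matrices"
  w
}

# per-row expansion of the block-diagonal group weight matrix D6
d6_diag <- function(weights, groups) {
  d6 <- numeric(length(unlist(groups)))
  for (k in seq_along(groups)) d6[groups[[k]]] <- weights$d6_blocks[k]
  d6
}

#' Evaluate the smoothed (reweighted) surrogate objective
#'
#' The pre-ADMM surrogate: every non-smooth norm replaced by its weighted
#' quadratic at the weights supplied, with the splitting copies identified
#' (`A = U`, `B_i = W_i`).
#'
#' @param state a model state.
#' @param cohort a `longitudinal_cohort`.
#' @param hp an [hyperparams()] object.
#' @param weights a [reweight()] result.
#' @return scalar surrogate value.
#' @export
eval_smoothed <- function(state, cohort, hp, weights) {
  res <- residual_matrices(state, cohort)
  g <- hp$gamma
  quad <- function(R, d) sum(d * rowSums(R^2))
  W1 <- unfold(state$W, 1L)
  W2 <- unfold(state$W, 2L)
  val <- quad(res$label, weights$d1) +
    g[1] * sum(vapply(seq_along(res$pca), function(i) {
      quad(res$pca[[i]], weights$d2[[i]])
    }, numeric(1))) +
    g[2] * quad(res$imaging, weights$d3) +
    g[3] * quad(res$snp, weights$d4) +
    g[4] * quad(res$align, weights$d5) +
    g[5] * sum(d6_diag(weights, cohort$snp_groups) * rowSums(state$H0^2)) +
    g[6] * sum(W1 * (weights$D7 %*% W1)) +
    g[6] * sum(W2 * (weights$D8 %*% W2)) +
    g[7] * sum(vapply(seq_len(ncol(state$U)), function(q) {
      sum(weights$d9[[q]] * state$U[, q]^2)
    }, numeric(1)))
  val
}

#' Evaluate the ADMM augmented Lagrangian
#'
#' The splitting form of the surrogate: copies `A` of `U` and `B_i` of `W_i`
#' enter the bilinear label and PCA terms exactly as the split objective is
#' written (one factor carries the original variable, the other the copy),
#' plus the four quadratic penalty/multiplier terms for the constraints
#' `F_l = Y_l`, `t(W_i) W_i = I`, `A = U`, `B_i = W_i`.
#'
#' @inheritParams eval_smoothed
#' @return scalar augmented Lagrangian value.
#' @export
eval_admm <- function(state, cohort, hp, weights) {
  g <- hp$gamma
  n <- length(state$W)
  l <- ncol(cohort$labels)
  Z <- enrich_all(cohort, state$W)

  R_label_A <- crossprod(state$A, state$G1) - state$Fmat
  R_label_U <- crossprod(state$U, state$G1) - state$Fmat
  val <- sum(weights$d1 * rowSums(R_label_A * R_label_U))

  for (i in seq_len(n)) {
    Xi <- cohort$histories[[i]]
    Wi <- state$W[[i]]; Bi <- state$B[[i]]
    RW <- Xi - Wi %*% crossprod(Wi, Xi)
    RB <- Xi - Bi %*% crossprod(Bi, Xi)
    val <- val + g[1] * sum(weights$d2[[i]] * rowSums(RW * RB))
  }

  R_img <- Z - state$H1 %*% state$G1
  val <- val + g[2] * sum(weights$d3 * rowSums(R_img^2))
  R_snp <- cohort$snp_matrix - state$H0 %*% state$G0
  val <- val + g[3] * sum(weights$d4 * rowSums(R_snp^2))
  R_al <- state$G1 - state$G0
  val <- val + g[4] * sum(weights$d5 * rowSums(R_al^2))
  val <- val + g[5] * sum(d6_diag(weights, cohort$snp_groups) *
                            rowSums(state$H0^2))

  W1 <- unfold(state$W, 1L)
  W2 <- unfold(state$W, 2L)
  B2 <- unfold(state$B, 2L)
  val <- val + g[6] * sum(W1 * (weights$D7 %*% W1))
  val <- val + g[6] * sum(W2 * (weights$D8 %*% B2))
  val <- val + g[7] * sum(vapply(seq_len(ncol(state$A)), function(q) {
    sum(weights$d9[[q]] * state$A[, q]^2)
  }, numeric(1)))

  Fl <- state$Fmat[, seq_len(l), drop = FALSE]
  val <- val + state$mu1 / 2 *
    sum((Fl - cohort$labels + state$Lambda1 / state$mu1)^2)
  for (i in seq_len(n)) {
    val <- val + state$mu2[i] / 2 *
      sum((crossprod(state$W[[i]], state$B[[i]]) - diag(hp$r1) +
             state$Lambda2[[i]] / state$mu2[i])^2)
    val <- val + state$mu4[i] / 2 *
      sum((state$B[[i]] - state$W[[i]] + state$Lambda4[[i]] / state$mu4[i])^2)
  }
  val <- val + state$mu3 / 2 *
    sum((state$A - state$U + state$Lambda3 / state$mu3)^2)
  val
}
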