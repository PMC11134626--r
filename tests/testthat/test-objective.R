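# assemble a ground-truth state on a noiseless cohort: every data-fit term
# must vanish exactly
truth_state <- function(sim, hp) {
  tr <- sim$truth
  n <- cohort_dims(sim$cohort)$n
  W <- rep(list(tr$subspaces_star[[1]]), n)
  list(
    W = W, B = W,
    H0 = tr$H0_star, G0 = tr$G_star,
    H1 = tr$latent_map, G1 = tr$G_star,
    U = tr$U_star,
    Fmat = t(tr$U_star) %*% tr$G_star,
    A = tr$U_star,
    Lambda1 = matrix(0, nrow(sim$cohort$labels), ncol(sim$cohort$labels)),
    Lambda2 = rep(list(matrix(0, hp$r1, hp$r1)), n),
    Lambda3 = matrix(0, hp$r2, nrow(sim$cohort$labels)),
    Lambda4 = rep(list(matrix(0, nrow(tr$subspaces_star[[1]]), hp$r1)), n),
    mu1 = 1, mu2 = rep(1, n), mu3 = 1, mu4 = rep(1, n)
  )
}

noiseless_sim <- function() {
  # p_discard_last = 0 so the last record sits exactly at the trajectory
  # endpoint that encodes the shared representation
  simulate_cohort(sim_config(n = 12, l = 10, d_modality = c(m = 8),
                             d_snp = 10, K = 2, c = 2, r1_true = 2,
                             r2_true = 2, noise_sd = 0,
                             p_discard_last = 0, seed = 21))
}

test_that("all residual terms vanish at the noiseless ground truth", {
  sim <- noiseless_sim()
  hp <- hyperparams(r1 = 2, r2 = 2, standardize = FALSE)
  tv <- eval_objective(truth_state(sim, hp), sim$cohort, hp)
  expect_equal(tv$label_fit, 0, tolerance = 1e-10)
  expect_equal(tv$pca_fit, 0, tolerance = 1e-8)
  expect_equal(tv$imaging_factor, 0, tolerance = 1e-8)
  expect_equal(tv$snp_factor, 0, tolerance = 1e-10)
  expect_equal(tv$align, 0)
})

test_that("the total is the gamma-weighted sum, recomputed from the norm ops", {
  ti <- tiny_instance()
  tv <- eval_objective(ti$state, ti$cohort, ti$hp)
  st <- ti$state; ch <- ti$cohort; g <- ti$hp$gamma
  Z <- enrich_all(ch, st$W)
  oracle <- l21_norm(st$Fmat - crossprod(st$U, st$G1)) +
    g[1] * sum(vapply(1:3, function(i) {
      Xi <- ch$histories[[i]]
      l21_norm(Xi - st$W[[i]] %*% crossprod(st$W[[i]], Xi))
    }, numeric(1))) +
    g[2] * l21_norm(Z - st$H1 %*% st$G1) +
    g[3] * l21_norm(ch$snp_matrix - st$H0 %*% st$G0) +
    g[4] * l21_norm(st$G1 - st$G0) +
    g[5] * group_l2_norm(st$H0, ch$snp_groups) +
    g[6] * (trace_norm(unfold(st$W, 1)) + trace_norm(unfold(st$W, 2))) +
    g[7] * sum(abs(st$U))
  expect_equal(tv$total, oracle, tolerance = 1e-10)

  hp0 <- ti$hp; hp0$gamma <- rep(0, 7)
  tv0 <- eval_objective(ti$state, ti$cohort, hp0)
  expect_equal(tv0$total, tv0$label_fit)
})

test_that("reweighting matches the stated closed forms", {
  ti <- tiny_instance()
  st <- ti$state
  # zero label residual: weight = 1 / (2 sqrt(delta))
  st0 <- st
  st0$Fmat <- crossprod(st0$U, st0$G1)
  w <- reweight(st0, ti$cohort, delta = 1e-4)
  expect_equal(unname(w$d1), rep(1 / (2e-2), nrow(st0$Fmat)))

  # a residual row of norm 3 at delta -> 0 gives weight 1/6
  st3 <- st
  st3$G0 <- st3$G1
  st3$G0[1, ] <- st3$G1[1, ] - c(3, 0, 0) # row residual (3,0,0)
  w3 <- reweight(st3, ti$cohort, delta = 1e-14)
  expect_equal(unname(w3$d5[1]), 1 / 6, tolerance = 1e-9)

  # W_(1) with orthonormal rows at delta = 0 gives D7 = I/2
  stw <- st
  stw$W <- list(matrix(c(1, 0, 0, 0, 0, 0, 1, 0), 4), # e1, e3
                matrix(c(0, 1, 0, 0, 0, 0, 0, 1), 4)) # e2, e4
  stw$B <- stw$W
  stw$Fmat <- stw$Fmat[, 1:2]  # match n = 2
  cohort2 <- tiny_cohort(n = 2)
  stw$G1 <- stw$G1[, 1:2]; stw$G0 <- stw$G0[, 1:2]
  ww <- reweight(stw, cohort2, delta = 0)
  expect_equal(ww$D7, diag(4) / 2, tolerance = 1e-10)

  # D6 block scalars
  expect_equal(unname(w$d6_blocks),
               unname(vapply(ti$cohort$snp_groups, function(g) {
                 0.5 / sqrt(sum(st0$H0[g, ]^2) + 1e-4)
               }, numeric(1))))
})

test_that("IRLS tangency: the weighted quadratic touches the L2,1 terms", {
  ti <- tiny_instance()
  st <- ti$state; ch <- ti$cohort
  w <- reweight(st, ch, delta = 1e-12)
  R <- crossprod(st$U, st$G1) - st$Fmat
  expect_equal(2 * sum(w$d1 * rowSums(R^2)), l21_norm(R), tolerance = 1e-6)
  Rs <- ch$snp_matrix - st$H0 %*% st$G0
  expect_equal(2 * sum(w$d4 * rowSums(Rs^2)), l21_norm(Rs), tolerance = 1e-6)
  # trace-norm tangency: tr(W1' D7 W1) = ||W1||_* / 2
  W1 <- unfold(st$W, 1)
  expect_equal(sum(W1 * (w$D7 %*% W1)), trace_norm(W1) / 2, tolerance = 1e-6)
  W2 <- unfold(st$W, 2)
  expect_equal(sum(W2 * (w$D8 %*% W2)), trace_norm(W2) / 2, tolerance = 1e-6)
  # group tangency
  d6 <- longenrich:::d6_diag(w, ch$snp_groups)
  expect_equal(2 * sum(d6 * rowSums(st$H0^2)),
               group_l2_norm(st$H0, ch$snp_groups), tolerance = 1e-6)
})

test_that("the smoothed surrogate matches a row-loop oracle", {
  ti <- tiny_instance()
  st <- ti$state; ch <- ti$cohort; hp <- ti$hp; w <- ti$weights
  val <- eval_smoothed(st, ch, hp, w)
  # oracle: every tr((R)' D (R)) term as an explicit row loop
  quad <- function(R, d) {
    s <- 0
    for (j in seq_len(nrow(R))) s <- s + d[j] * sum(R[j, ]^2)
    s
  }
  g <- hp$gamma
  Z <- enrich_all(ch, st$W)
  oracle <- quad(crossprod(st$U, st$G1) - st$Fmat, w$d1)
  for (i in 1:3) {
    Xi <- ch$histories[[i]]
    oracle <- oracle + g[1] *
      quad(Xi - st$W[[i]] %*% crossprod(st$W[[i]], Xi), w$d2[[i]])
  }
  oracle <- oracle + g[2] * quad(Z - st$H1 %*% st$G1, w$d3) +
    g[3] * quad(ch$snp_matrix - st$H0 %*% st$G0, w$d4) +
    g[4] * quad(st$G1 - st$G0, w$d5) +
    g[5] * quad(st$H0, longenrich:::d6_diag(w, ch$snp_groups)) +
    g[6] * sum(diag(t(unfold(st$W, 1)) %*% w$D7 %*% unfold(st$W, 1))) +
    g[6] * sum(diag(t(unfold(st$W, 2)) %*% w$D8 %*% unfold(st$W, 2))) +
    g[7] * sum(vapply(seq_len(ncol(st$U)), function(q) {
      sum(w$d9[[q]] * st$U[, q]^2)
    }, numeric(1)))
  expect_equal(val, oracle, tolerance = 1e-10)

  # gammas = 0 leaves only the weighted label term
  hp0 <- hp; hp0$gamma <- rep(0, 7)
  expect_equal(eval_smoothed(st, ch, hp0, w),
               quad(crossprod(st$U, st$G1) - st$Fmat, w$d1),
               tolerance = 1e-12)
})

test_that("the augmented Lagrangian coincides with the surrogate at A=U, B=W", {
  ti <- tiny_instance()
  st <- ti$state
  st$A <- st$U
  st$B <- st$W
  # make constrained quantities feasible so the penalty terms vanish
  l <- ncol(ti$cohort$labels)
  st$Fmat[, seq_len(l)] <- ti$cohort$labels
  st$W <- lapply(st$W, function(Wi) qr.Q(qr(Wi)))
  st$B <- st$W
  w <- reweight(st, ti$cohort, ti$hp$delta)
  expect_equal(eval_admm(st, ti$cohort, ti$hp, w),
               eval_smoothed(st, ti$cohort, ti$hp, w), tolerance = 1e-10)
})
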