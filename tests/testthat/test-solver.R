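small_sim <- function(seed = 13, ...) {
  simulate_cohort(sim_config(n = 16, l = 12, d_modality = c(m = 8),
                             d_snp = 10, K = 2, c = 2, r1_true = 2,
                             r2_true = 2, seed = seed, ...))
}

test_that("initialization is deterministic, orthonormal and label-feasible", {
  cohort <- tiny_cohort(n = 4, d = 5, n_visits = 4, seed = 3)
  hp <- hyperparams(r1 = 2, r2 = 2, standardize = FALSE, seed = 9)
  s1 <- init_state(cohort, hp)
  s2 <- init_state(cohort, hp)
  expect_identical(s1, s2)
  for (Wi in s1$W) {
    expect_equal(crossprod(Wi), diag(2), tolerance = 1e-10)
  }
  expect_equal(s1$Fmat[, 1:2], cohort$labels, ignore_attr = TRUE)
  expect_equal(s1$Fmat[, 3:4], matrix(0, 1, 2), ignore_attr = TRUE)
  expect_identical(s1$A, s1$U)
  expect_error(init_state(cohort, hyperparams(r1 = 6, r2 = 2)), "r1")
  expect_error(init_state(cohort, hyperparams(r1 = 2, r2 = 5)), "r2")
})

test_that("every block update matches a generic numerical minimizer", {
  ti <- tiny_instance()
  v0 <- eval_admm(ti$state, ti$cohort, ti$hp, ti$weights)
  for (blk in solver_blocks) {
    cur <- get_block(ti$state, blk)
    f <- function(v) {
      eval_admm(set_block(ti$state, blk, matrix(v, nrow(cur))),
                ti$cohort, ti$hp, ti$weights)
    }
    opt <- optim(as.vector(cur), f, method = "BFGS",
                 control = list(maxit = 5000, reltol = 1e-15))
    upd <- update_block(ti$state, ti$cohort, ti$hp, ti$weights, blk,
                        i = if (blk %in% c("W", "B")) 1 else NULL)
    mine <- get_block(upd, blk)
    expect_equal(mine, matrix(opt$par, nrow(cur)), tolerance = 1e-5,
                 ignore_attr = TRUE, label = paste("block", blk))
    v1 <- eval_admm(upd, ti$cohort, ti$hp, ti$weights)
    expect_lte(v1, v0 + 1e-10)
  }
})

test_that("block updates are idempotent (exact stationarity)", {
  ti <- tiny_instance()
  for (blk in solver_blocks) {
    once <- update_block(ti$state, ti$cohort, ti$hp, ti$weights, blk,
                         i = if (blk %in% c("W", "B")) 1 else NULL)
    twice <- update_block(once, ti$cohort, ti$hp, ti$weights, blk,
                          i = if (blk %in% c("W", "B")) 1 else NULL)
    expect_equal(get_block(once, blk), get_block(twice, blk),
                 tolerance = 1e-8, label = paste("block", blk))
  }
})

test_that("H1 update reduces to least squares when D3 is proportional to I", {
  ti <- tiny_instance()
  st <- ti$state
  w <- ti$weights
  w$d3 <- rep(0.7, length(w$d3))
  upd <- update_block(st, ti$cohort, ti$hp, w, "H1")
  Z <- enrich_all(ti$cohort, st$W)
  oracle <- Z %*% t(st$G1) %*% solve(tcrossprod(st$G1))
  expect_equal(upd$H1, oracle, tolerance = 1e-8)
})

test_that("multiplier updates follow dual ascent with penalty growth", {
  ti <- tiny_instance(perturb = FALSE)
  st <- ti$state
  hp <- ti$hp
  # at init: F_l = Y_l, A = U, B = W with orthonormal W: all residuals zero
  up <- update_multipliers(st, ti$cohort, hp)
  expect_equal(up$Lambda1, st$Lambda1)
  expect_equal(up$Lambda3, st$Lambda3)
  expect_equal(up$mu1, st$mu1 * hp$rho[1])
  expect_equal(up$mu3, st$mu3 * hp$rho[3])
  expect_equal(up$mu4, st$mu4 * hp$rho[4])

  # rho = 1 leaves penalties unchanged
  hp1 <- hp; hp1$rho <- rep(1, 4)
  up1 <- update_multipliers(st, ti$cohort, hp1)
  expect_equal(up1$mu1, st$mu1)

  # scalar dual ascent: lambda <- lambda + mu * residual
  st3 <- st
  st3$mu3 <- 2
  st3$A <- st3$U + 3 / 2  # residual A - U = 1.5 everywhere, mu = 2 -> +3
  up3 <- update_multipliers(st3, ti$cohort, hp)
  expect_equal(up3$Lambda3, st3$Lambda3 + 3)

  # growth is capped at mu_max
  stc <- st; stc$mu1 <- hp$mu_max
  expect_equal(update_multipliers(stc, ti$cohort, hp)$mu1, hp$mu_max)
})

test_that("fit descends, reaches feasibility and is deterministic", {
  sim <- small_sim()
  hp <- hyperparams(r1 = 2, r2 = 2, max_outer = 5, max_inner = 60, seed = 2)
  fit1 <- fit_enrichment(sim$cohort, hp)
  fit2 <- fit_enrichment(sim$cohort, hp)
  expect_identical(fit1$objective_history, fit2$objective_history)
  obj <- fit1$objective_history
  expect_true(all(is.finite(obj)))
  expect_true(all(diff(obj) <= 1e-6 * (1 + abs(obj[-length(obj)]))))
  # the strict 1e-4 feasibility bound is asserted at the acceptance sizes in
  # test-acceptance.R; this small smoke instance gets a looser bound
  res <- fit1$residual_history[nrow(fit1$residual_history), ]
  expect_true(all(res < 1e-3))
  expect_equal(fit1$Z, enrich_all(
    longenrich:::standardize_cohort(sim$cohort)$cohort, fit1$state$W))
})

test_that("labels influence the unlabeled predictions (semi-supervision)", {
  sim <- small_sim(seed = 17)
  hp <- hyperparams(r1 = 2, r2 = 2, max_outer = 2, max_inner = 30, seed = 2)
  fit1 <- fit_enrichment(sim$cohort, hp)
  cohort2 <- sim$cohort
  set.seed(1)
  cohort2$labels <- cohort2$labels + rnorm(length(cohort2$labels))
  fit2 <- fit_enrichment(cohort2, hp)
  Fu1 <- fit1$state$Fmat[, 13:16]
  Fu2 <- fit2$state$Fmat[, 13:16]
  expect_gt(max(abs(Fu1 - Fu2)), 1e-6)
})

test_that("decoupled robust PCA recovers the history subspace", {
  # gamma2..7 = 0, gamma1 = 1: the problem separates into per-participant
  # robust PCA; on noiseless rank-r1 histories the fitted span must match
  # the SVD span
  sim <- small_sim(seed = 23, noise_sd = 0, traj_jitter_sd = 0.5,
                   visit_count_range = c(6, 6), p_discard_last = 0)
  # initial penalties on the order of the data-term curvature gamma1*||X X'||,
  # so the copy dynamics are stable from the first sweep
  hp <- hyperparams(gamma1 = 1, gamma2 = 0, gamma3 = 0, gamma4 = 0,
                    gamma5 = 0, gamma6 = 0, gamma7 = 0,
                    r1 = 2, r2 = 2, max_outer = 4, max_inner = 80,
                    mu2_init = 50, mu4_init = 50,
                    standardize = FALSE, seed = 5)
  fit <- fit_enrichment(sim$cohort, hp)
  for (i in seq_along(fit$state$W)) {
    sv <- svd(sim$cohort$histories[[i]])$u[, 1:2]
    expect_lte(principal_angle(fit$state$W[[i]], sv), 1e-3)
  }
})

test_that("with identity weights the W step solves classical PCA", {
  sim <- small_sim(seed = 29, visit_count_range = c(6, 6), p_discard_last = 0)
  hp <- hyperparams(gamma1 = 1, gamma2 = 0, gamma3 = 0, gamma4 = 0,
                    gamma5 = 0, gamma6 = 0, gamma7 = 0,
                    r1 = 2, r2 = 2, max_outer = 1, max_inner = 200,
                    mu2_init = 50, mu4_init = 50,
                    tol_residual = 1e-9, standardize = FALSE, seed = 5)
  fit <- fit_enrichment(sim$cohort, hp, weights_mode = "identity")
  for (i in seq_along(fit$state$W)) {
    Xi <- sim$cohort$histories[[i]]
    pca <- svd(Xi)$u[, 1:2]
    expect_lte(norm(projector(fit$state$W[[i]]) - projector(pca), "F"), 1e-6)
  }
})

test_that("per-iteration W cost grows with the imaging dimension", {
  time_w <- function(d) {
    cohort <- tiny_cohort(n = 6, d = d, d_snp = 5, n_visits = 5, seed = 1)
    hp <- hyperparams(r1 = 3, r2 = 2, standardize = FALSE, seed = 1)
    state <- init_state(cohort, hp)
    w <- reweight(state, cohort, hp$delta)
    # median of several sweeps to damp scheduler noise
    median(vapply(1:5, function(k) {
      system.time(for (i in 1:6) {
        state <- update_block(state, cohort, hp, w, "W", i)
      })[["elapsed"]]
    }, numeric(1)))
  }
  expect_gt(time_w(80), 1.2 * time_w(20))
})
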