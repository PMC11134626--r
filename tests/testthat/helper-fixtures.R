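# Shared fixtures: everything is built in code, seeded, and small.

rand_mat <- function(nr, nc, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(nr * nc), nr, nc)
}

# a tiny valid cohort: n participants, d imaging features, d_snp SNPs
tiny_cohort <- function(n = 3, d = 4, d_snp = 5, c = 1, l = 2,
                        n_visits = 3, seed = 42) {
  set.seed(seed)
  longitudinal_cohort(
    histories = lapply(seq_len(n), function(i) rand_mat(d, n_visits)),
    last_records = rand_mat(d, n),
    modality_slices = list(all = seq_len(d)),
    snp_matrix = rand_mat(d_snp, n),
    snp_groups = list(g1 = 1:2, g2 = 3:d_snp),
    labels = rand_mat(c, l)
  )
}

# solver test instance matching the contract-check size
# (n = 3, d = 4, r1 = 2, r2 = 2, c = 1), with moderate gammas so every
# block subproblem of the augmented Lagrangian is bounded and convex
tiny_instance <- function(seed = 7, perturb = TRUE) {
  cohort <- tiny_cohort(seed = seed)
  hp <- hyperparams(gamma1 = 0.05, gamma2 = 0.5, gamma3 = 0.5,
                    gamma4 = 0.5, gamma5 = 0.5, gamma6 = 0.2, gamma7 = 0.5,
                    r1 = 2, r2 = 2, delta = 1e-4,
                    standardize = FALSE, seed = seed)
  state <- init_state(cohort, hp)
  if (perturb) {
    set.seed(seed + 1)
    jig <- function(M, s = 0.2) M + s * rand_mat(nrow(M), ncol(M))
    state$U <- jig(state$U); state$A <- state$U
    state$H0 <- jig(state$H0); state$H1 <- jig(state$H1)
    state$G0 <- jig(state$G0); state$G1 <- jig(state$G1)
    state$Fmat <- jig(state$Fmat)
    state$W <- lapply(state$W, jig, s = 0.1)
    state$B <- state$W
  }
  weights <- reweight(state, cohort, hp$delta)
  list(cohort = cohort, hp = hp, state = state, weights = weights)
}

get_block <- function(st, blk, i = 1) {
  switch(blk, U = st$U, A = st$A, F = st$Fmat, H1 = st$H1, G1 = st$G1,
         H0 = st$H0, G0 = st$G0, W = st$W[[i]], B = st$B[[i]])
}

set_block <- function(st, blk, val, i = 1) {
  switch(blk, U = st$U <- val, A = st$A <- val, F = st$Fmat <- val,
         H1 = st$H1 <- val, G1 = st$G1 <- val, H0 = st$H0 <- val,
         G0 = st$G0 <- val, W = st$W[[i]] <- val, B = st$B[[i]] <- val)
  st
}

solver_blocks <- c("U", "A", "F", "H1", "G1", "H0", "G0", "W", "B")

# largest principal angle between the column spaces of A and B
principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(min(1, max(0, min(s))))
}

projector <- function(W) tcrossprod(qr.Q(qr(W)))
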