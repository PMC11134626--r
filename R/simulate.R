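#' Configuration of the synthetic cohort generator
#'
#' The generator emulates the statistical structure the enrichment model
#' assumes: a shared low-dimensional participant representation drives the
#' imaging, genetic and clinical views; imaging visits follow a smooth
#' low-rank trajectory per participant whose endpoint encodes that shared
#' representation; the SNP loading matrix is group-sparse; visit counts vary
#' and the latest scan is discarded with a fixed probability before the
#' "last record" is taken (mirroring a cohort whose final scan is missing
#' for half the participants).
#'
#' @param n participants; `l` of them labeled.
#' @param l labeled (training) participants, placed first.
#' @param d_modality named integer vector of feature counts per imaging
#'   modality (concatenated into the `d`-dimensional feature vector).
#' @param d_snp number of SNP features.
#' @param K number of SNP groups (equal-sized up to remainder).
#' @param c number of clinical scores.
#' @param r1_true rank of each participant's true imaging subspace.
#' @param r2_true dimension of the shared latent representation.
#' @param visit_count_range integer `c(min, max)` of total scans per
#'   participant before any discard (history length is total - 1).
#' @param p_discard_last probability that the latest scan is removed before
#'   the last record is taken.
#' @param noise_sd measurement noise s.d. added to every view (signal is
#'   unit scale).
#' @param traj_jitter_sd latent-space jitter of history visits around the
#'   linear trajectory, so histories genuinely span `r1_true` dimensions.
#' @param outlier_fraction,outlier_scale defaults passed to
#'   [inject_outliers()] when `outlier_fraction > 0`.
#' @param active_group_count SNP groups with nonzero true loadings.
#' @param seed integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n = 80L, l = 64L,
                       d_modality = c(VBM = 45L, FS = 45L),
                       d_snp = 40L, K = 8L, c = 2L,
                       r1_true = 3L, r2_true = 3L,
                       visit_count_range = c(4L, 4L),
                       p_discard_last = 0.5,
                       noise_sd = 0.5, traj_jitter_sd = 0.3,
                       outlier_fraction = 0, outlier_scale = 5,
                       active_group_count = 2L, seed = 1L) {
  cfg <- list(
    n = as.integer(n), l = as.integer(l),
    d_modality = d_modality, d = sum(d_modality),
    d_snp = as.integer(d_snp), K = as.integer(K), c = as.integer(c),
    r1_true = as.integer(r1_true), r2_true = as.integer(r2_true),
    visit_count_range = as.integer(visit_count_range),
    p_discard_last = p_discard_last,
    noise_sd = noise_sd, traj_jitter_sd = traj_jitter_sd,
    outlier_fraction = outlier_fraction, outlier_scale = outlier_scale,
    active_group_count = as.integer(active_group_count),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n >= 2, cfg$l >= 1, cfg$l <= cfg$n, cfg$d >= 1, cfg$d_snp >= cfg$K,
    cfg$K >= 1, cfg$c >= 1, cfg$r1_true >= 1, cfg$r2_true >= 1,
    cfg$p_discard_last >= 0, cfg$p_discard_last <= 1,
    cfg$outlier_fraction >= 0, cfg$outlier_fraction <= 1,
    cfg$noise_sd >= 0, cfg$traj_jitter_sd >= 0,
    cfg$active_group_count <= cfg$K,
    length(cfg$visit_count_range) == 2L,
    cfg$visit_count_range[1] >= 2L,
    cfg$visit_count_range[2] >= cfg$visit_count_range[1]
  )
  class(cfg) <- "sim_config"
  cfg
}

# orthonormal basis with a deterministic sign convention
rand_orthonormal <- function(nr, nc) {
  Q <- qr.Q(qr(matrix(stats::rnorm(nr * nc), nr, nc)))
  fix_svd_signs(Q)
}

# make the largest-magnitude entry of each column positive (determinism
# under the sign ambiguity of SVD/QR factors)
fix_svd_signs <- function(Q) {
  for (j in seq_len(ncol(Q))) {
    p <- which.max(abs(Q[, j]))
    if (Q[p, j] < 0) Q[, j] <- -Q[, j]
  }
  Q
}

#' Simulate a cohort with known ground truth
#'
#' Deterministic given `cfg$seed`.  A shared representation `G_star`
#' (`r2_true x n`) generates all three views: `X_SNP = H0_star G_star +
#' noise` with `H0_star` nonzero only on `active_group_count` groups;
#' clinical scores `Y_l = t(U_star) G_star[, 1:l] + noise`; and imaging
#' visits `Q (s_ij) + noise` where the latent trajectory `s_ij` drifts
#' linearly toward an endpoint `M g_i`, so the last record encodes the
#' participant's shared representation and the history informs it.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `cohort` (a valid `longitudinal_cohort`) and
#'   `truth` (list: `G_star`, `H0_star`, `U_star`, `active_groups`,
#'   `subspaces_star` — the per-participant true imaging basis —, and the
#'   discard indicator `discarded`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n; d <- cfg$d
    G_star <- matrix(stats::rnorm(cfg$r2_true * n), cfg$r2_true, n)

    # group-sparse SNP loadings
    sizes <- rep(cfg$d_snp %/% cfg$K, cfg$K)
    if (cfg$d_snp %% cfg$K) {
      sizes[seq_len(cfg$d_snp %% cfg$K)] <- sizes[seq_len(cfg$d_snp %% cfg$K)] + 1L
    }
    ends <- cumsum(sizes)
    snp_groups <- lapply(seq_len(cfg$K),
                         function(k) as.integer((ends[k] - sizes[k] + 1):ends[k]))
    active <- sort(sample.int(cfg$K, cfg$active_group_count))
    H0_star <- matrix(0, cfg$d_snp, cfg$r2_true)
    for (k in active) {
      H0_star[snp_groups[[k]], ] <-
        matrix(stats::rnorm(sizes[k] * cfg$r2_true), sizes[k])
    }
    snp_matrix <- H0_star %*% G_star +
      cfg$noise_sd * matrix(stats::rnorm(cfg$d_snp * n), cfg$d_snp, n)

    U_star <- matrix(stats::rnorm(cfg$r2_true * cfg$c), cfg$r2_true, cfg$c)
    labels <- t(U_star) %*% G_star[, seq_len(cfg$l), drop = FALSE] +
      cfg$noise_sd * matrix(stats::rnorm(cfg$c * cfg$l), cfg$c, cfg$l)

    # shared imaging basis and latent-to-imaging map
    Q <- rand_orthonormal(d, cfg$r1_true)
    M <- matrix(stats::rnorm(cfg$r1_true * cfg$r2_true), cfg$r1_true)

    visit_choices <- seq(cfg$visit_count_range[1], cfg$visit_count_range[2])
    m_total <- visit_choices[sample.int(length(visit_choices), n,
                                        replace = TRUE)]
    discarded <- stats::runif(n) < cfg$p_discard_last
    m_eff <- m_total - as.integer(discarded)
    if (any(m_eff < 2L)) {
      stop(sprintf("participant %d is left with %d visit(s) after discard; increase visit_count_range",
                   which(m_eff < 2L)[1], m_eff[which(m_eff < 2L)[1]]))
    }

    histories <- vector("list", n)
    last_records <- matrix(0, d, n)
    for (i in seq_len(n)) {
      target <- M %*% G_star[, i]
      start <- stats::rnorm(cfg$r1_true)
      m <- m_eff[i]
      # latent trajectory over the ORIGINAL visit grid, truncated by discard
      S <- sapply(seq_len(m), function(j) {
        t <- (j - 1) / (m_total[i] - 1)
        drop(start + t * (target - start))
      })
      S <- matrix(S, cfg$r1_true, m)
      if (m > 1L && cfg$traj_jitter_sd > 0) {
        S[, -m] <- S[, -m, drop = FALSE] +
          cfg$traj_jitter_sd * matrix(stats::rnorm(cfg$r1_true * (m - 1)),
                                      cfg$r1_true)
      }
      V <- Q %*% S + cfg$noise_sd * matrix(stats::rnorm(d * m), d, m)
      histories[[i]] <- V[, -m, drop = FALSE]
      last_records[, i] <- V[, m]
    }

    slices <- split(seq_len(d),
                    rep(seq_along(cfg$d_modality), cfg$d_modality))
    names(slices) <- names(cfg$d_modality)

    cohort <- longitudinal_cohort(
      histories = histories, last_records = last_records,
      modality_slices = slices, snp_matrix = snp_matrix,
      snp_groups = snp_groups, labels = labels
    )
    if (cfg$outlier_fraction > 0) {
      cohort <- inject_outliers(cohort, cfg$outlier_fraction,
                                cfg$outlier_scale, seed = cfg$seed + 1L)
    }
    list(
      cohort = cohort,
      truth = list(
        G_star = G_star, H0_star = H0_star, U_star = U_star,
        active_groups = active,
        subspaces_star = rep(list(Q), n),
        latent_map = M, discarded = discarded
      )
    )
  })
}

#' Corrupt a fraction of visit records with heavy-tailed noise
#'
#' Whole visit columns (pooled over histories and last records) are chosen
#' without replacement and perturbed additively with t(2)-distributed noise
#' scaled by `scale` times the per-feature standard deviation; untouched
#' columns are bitwise equal to the input.  Column-wise corruption is what
#' the row/column-robust losses of the model are designed to resist.
#'
#' @param cohort a `longitudinal_cohort`.
#' @param fraction share of visit columns to corrupt, in `[0, 1]`.
#' @param scale multiple of the per-feature s.d. used as noise scale.
#' @param seed integer seed.
#' @return the corrupted cohort; `attr(, "outlier_columns")` records which
#'   (participant, visit) columns were touched (`visit = 0` marks the last
#'   record).
#' @export
inject_outliers <- function(cohort, fraction, scale, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  n_i <- vapply(cohort$histories, ncol, integer(1))
  # pooled column index: per participant the history columns then the last record
  cols <- do.call(rbind, lapply(seq_along(n_i), function(i) {
    cbind(participant = i, visit = c(seq_len(n_i[i]), 0L))
  }))
  total <- nrow(cols)
  m <- round(fraction * total)
  if (m == 0L || scale == 0) {
    attr(cohort, "outlier_columns") <- cols[integer(0), , drop = FALSE]
    return(cohort)
  }
  feat_sd <- apply(cohort$last_records, 1, stats::sd)
  feat_sd[feat_sd == 0] <- 1
  with_seed(seed, {
    pick <- sample.int(total, m)
    for (r in pick) {
      i <- cols[r, "participant"]; v <- cols[r, "visit"]
      noise <- scale * feat_sd * stats::rt(length(feat_sd), df = 2)
      if (v == 0L) {
        cohort$last_records[, i] <- cohort$last_records[, i] + noise
      } else {
        cohort$histories[[i]][, v] <- cohort$histories[[i]][, v] + noise
      }
    }
    attr(cohort, "outlier_columns") <- cols[pick, , drop = FALSE]
    cohort
  })
}

#' Write simulation ground truth as a JSON sidecar
#'
#' @param truth the `truth` element of [simulate_cohort()] output.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(
    G_star = truth$G_star, H0_star = truth$H0_star, U_star = truth$U_star,
    active_groups = truth$active_groups, latent_map = truth$latent_map,
    discarded = truth$discarded,
    subspace_star = truth$subspaces_star[[1]]
  )
  jsonlite::write_json(out, path, digits = NA)
  invisible(path)
}
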