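#' Construct a longitudinal imaging-genetic cohort
#'
#' The container shared by every function in the package.  Features are rows
#' and participants are columns throughout, so each formula of the model can
#' be transcribed without transposition bookkeeping.  Participant `i` is
#' described by a history matrix `X_i` (d features by `n_i` visits, baseline
#' through second-last visit), a last-visit record `x_i` (column `i` of
#' `last_records`), a static SNP profile (column `i` of `snp_matrix`) and,
#' for the first `l` participants only, a column of clinical scores.
#'
#' Missing visits are represented by absence (ragged `n_i`), never by NaN
#' imputation: the point of enrichment is to handle variable-length records.
#'
#' @param histories list of numeric matrices, one per participant; matrix `i`
#'   has `d` rows and `n_i >= 1` columns (all visits before the last one).
#' @param last_records numeric matrix `d x n`; column `i` is the most recent
#'   visit of participant `i`, the record that gets enriched.
#' @param modality_slices named list of contiguous, disjoint integer ranges
#'   (e.g. `list(VBM = 1:15, FS = 16:30)`) partitioning the `d` feature rows.
#' @param snp_matrix numeric matrix `d_SNP x n` of static genotype features.
#' @param snp_groups list of integer vectors partitioning `1:d_SNP` into `K`
#'   ordered groups (e.g. linkage-disequilibrium or gene groups).
#' @param labels numeric matrix `c x l` of clinical scores for the first `l`
#'   participants (the labeled/training subset).
#' @param ids character vector of participant identifiers, labeled first.
#'
#' @return an object of class `longitudinal_cohort` (a validated list).
#' @seealso [validate_cohort()], [simulate_cohort()], [read_cohort()]
#' @export
longitudinal_cohort <- function(histories, last_records, modality_slices,
                                snp_matrix, snp_groups, labels,
                                ids = NULL) {
  last_records <- as.matrix(last_records)
  snp_matrix <- as.matrix(snp_matrix)
  labels <- as.matrix(labels)
  if (is.null(ids)) ids <- paste0("P", seq_len(ncol(last_records)))
  cohort <- structure(
    list(
      histories = lapply(histories, as.matrix),
      last_records = last_records,
      modality_slices = modality_slices,
      snp_matrix = snp_matrix,
      snp_groups = snp_groups,
      labels = labels,
      ids = as.character(ids)
    ),
    class = "longitudinal_cohort"
  )
  report <- validate_cohort(cohort)
  if (length(report) > 0L) {
    stop("invalid cohort:\n  ", paste(report, collapse = "\n  "), call. = FALSE)
  }
  cohort
}

#' Cohort dimensions
#'
#' @param cohort a `longitudinal_cohort`.
#' @return named list with `n`, `l`, `d`, `d_snp`, `K`, `c`, and the vector of
#'   history lengths `n_i`.
#' @export
cohort_dims <- function(cohort) {
  list(
    n = ncol(cohort$last_records),
    l = ncol(cohort$labels),
    d = nrow(cohort$last_records),
    d_snp = nrow(cohort$snp_matrix),
    K = length(cohort$snp_groups),
    c = nrow(cohort$labels),
    n_i = vapply(cohort$histories, ncol, integer(1))
  )
}

#' Validate a cohort against the model's invariants
#'
#' Pure check: returns a character vector listing every violated invariant
#' (shape mismatches, empty histories, non-partition SNP group maps,
#' non-finite entries); an empty vector means the cohort is valid.  Never
#' mutates its input and never throws, so callers decide whether to abort.
#'
#' @param cohort a list shaped like [longitudinal_cohort()] output.
#' @return character vector of human-readable violations (possibly empty).
#' @export
validate_cohort <- function(cohort) {
  bad <- character(0)
  note <- function(msg) bad <<- c(bad, msg)

  if (!is.list(cohort$histories) || length(cohort$histories) == 0L) {
    note("histories must be a nonempty list of matrices")
    return(bad)
  }
  n <- ncol(cohort$last_records)
  d <- nrow(cohort$last_records)
  if (length(cohort$histories) != n) {
    note(sprintf("histories has %d entries but last_records has %d columns",
                 length(cohort$histories), n))
  }
  for (i in seq_along(cohort$histories)) {
    Xi <- cohort$histories[[i]]
    if (!is.matrix(Xi) || !is.numeric(Xi)) {
      note(sprintf("history %d is not a numeric matrix", i))
      next
    }
    if (nrow(Xi) != d) {
      note(sprintf("history %d has %d rows, expected d = %d", i, nrow(Xi), d))
    }
    if (ncol(Xi) < 1L) {
      note(sprintf("history %d violates n_i >= 1 (n_i < 1: participant needs at least 2 total records)", i))
    }
    if (length(Xi) && !all(is.finite(Xi))) {
      note(sprintf("history %d contains NaN/Inf entries", i))
    }
  }
  if (!all(is.finite(cohort$last_records))) note("last_records contains NaN/Inf entries")
  if (!all(is.finite(cohort$snp_matrix))) note("snp_matrix contains NaN/Inf entries")
  if (!all(is.finite(cohort$labels))) note("labels contains NaN/Inf entries")

  if (ncol(cohort$snp_matrix) != n) {
    note(sprintf("snp_matrix has %d columns, expected n = %d",
                 ncol(cohort$snp_matrix), n))
  }
  l <- ncol(cohort$labels)
  if (l < 1L || l > n) {
    note(sprintf("labels has %d columns; need 1 <= l <= n = %d", l, n))
  }

  # snp_groups must be an ordered disjoint cover of 1..d_SNP
  d_snp <- nrow(cohort$snp_matrix)
  idx <- unlist(cohort$snp_groups, use.names = FALSE)
  if (length(idx) != d_snp || anyDuplicated(idx) ||
      !setequal(idx, seq_len(d_snp))) {
    note(sprintf("snp_groups is not a disjoint partition covering 1..%d", d_snp))
  }

  # modality slices must be disjoint and cover 1..d
  midx <- unlist(cohort$modality_slices, use.names = FALSE)
  if (length(midx) != d || anyDuplicated(midx) || !setequal(midx, seq_len(d))) {
    note(sprintf("modality_slices do not partition feature rows 1..%d", d))
  }

  if (length(cohort$ids) != n) {
    note(sprintf("ids has length %d, expected n = %d", length(cohort$ids), n))
  }
  bad
}

#' @export
print.longitudinal_cohort <- function(x, ...) {
  dm <- cohort_dims(x)
  cat("Longitudinal imaging-genetic cohort\n")
  cat(sprintf("  participants : %d (%d labeled)\n", dm$n, dm$l))
  cat(sprintf("  imaging dim  : %d (%s)\n", dm$d,
              paste(sprintf("%s=%d", names(x$modality_slices),
                            lengths(x$modality_slices)), collapse = ", ")))
  cat(sprintf("  SNPs         : %d in %d groups\n", dm$d_snp, dm$K))
  cat(sprintf("  scores       : %d\n", dm$c))
  cat(sprintf("  visits/history: %d-%d\n", min(dm$n_i), max(dm$n_i)))
  invisible(x)
}

#' Hyperparameters of the enrichment model
#'
#' @param gamma1,gamma2,gamma3,gamma4,gamma5,gamma6,gamma7 nonnegative weights
#'   of the objective terms: robust per-participant PCA fit, enriched-imaging
#'   factorization, SNP factorization, latent alignment, group sparsity on SNP
#'   loadings, trace-norm coupling of the projections, and L1 sparsity of the
#'   regression weights.  Defaults are the tuned values reported for the ADNI
#'   experiments.
#' @param r1 enriched imaging dimension (columns of each projection `W_i`).
#' @param r2 shared latent participant dimension.
#' @param delta smoothing constant (> 0) of the reweighted surrogate.
#' @param rho1,rho2,rho3,rho4 geometric growth factors (>= 1) of the four
#'   ADMM penalty parameters.
#' @param mu1_init,mu2_init,mu3_init,mu4_init initial penalties (> 0).
#' @param mu_max cap on penalty growth, to avoid ill-conditioned subproblems.
#' @param max_outer,max_inner iteration limits of the reweighting loop and of
#'   the inner ADMM.
#' @param tol_obj relative objective-change tolerance of the outer loop.
#' @param tol_residual tolerance on the four ADMM constraint residuals.
#' @param standardize z-score imaging and SNP features before fitting.
#' @param seed integer seed for the randomized parts of initialization.
#' @return object of class `enrich_hyperparams`.
#' @export
hyperparams <- function(gamma1 = 1e-1, gamma2 = 1e-4, gamma3 = 1e-2,
                        gamma4 = 1e-3, gamma5 = 1e-1, gamma6 = 1e-1,
                        gamma7 = 1e-1,
                        r1 = 5L, r2 = 3L, delta = 1e-8,
                        rho1 = 1.05, rho2 = 1.05, rho3 = 1.15, rho4 = 1.15,
                        mu1_init = 1, mu2_init = 1, mu3_init = 1,
                        mu4_init = 1, mu_max = 1e8,
                        max_outer = 50L, max_inner = 100L,
                        tol_obj = 1e-6, tol_residual = 1e-6,
                        standardize = TRUE, seed = 1L) {
  hp <- list(
    gamma = c(gamma1, gamma2, gamma3, gamma4, gamma5, gamma6, gamma7),
    r1 = as.integer(r1), r2 = as.integer(r2), delta = delta,
    rho = c(rho1, rho2, rho3, rho4),
    mu_init = c(mu1_init, mu2_init, mu3_init, mu4_init),
    mu_max = mu_max,
    max_outer = as.integer(max_outer), max_inner = as.integer(max_inner),
    tol_obj = tol_obj, tol_residual = tol_residual,
    standardize = isTRUE(standardize), seed = as.integer(seed)
  )
  stopifnot(all(hp$gamma >= 0), hp$delta > 0, all(hp$rho >= 1),
            all(hp$mu_init > 0), hp$r1 >= 1, hp$r2 >= 1,
            hp$max_outer >= 1, hp$max_inner >= 1,
            hp$tol_obj > 0, hp$tol_residual > 0)
  class(hp) <- "enrich_hyperparams"
  hp
}

#' @export
print.enrich_hyperparams <- function(x, ...) {
  cat("Enrichment hyperparameters\n")
  cat("  gamma1..7:", paste(format(x$gamma, digits = 3), collapse = " "), "\n")
  cat(sprintf("  r1 = %d, r2 = %d, delta = %g\n", x$r1, x$r2, x$delta))
  cat("  rho1..4  :", paste(format(x$rho), collapse = " "),
      " mu_init:", paste(format(x$mu_init), collapse = " "), "\n")
  cat(sprintf("  outer <= %d (tol %g), inner <= %d (residual tol %g)\n",
              x$max_outer, x$tol_obj, x$max_inner, x$tol_residual))
  invisible(x)
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
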