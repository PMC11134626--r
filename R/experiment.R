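#' Reorder the participants of a cohort
#'
#' @param cohort a `longitudinal_cohort` in which every participant is
#'   labeled (`l = n`), so any permutation is valid.
#' @param perm integer permutation of `1:n`.
#' @return the permuted cohort.
#' @export
reorder_cohort <- function(cohort, perm) {
  dm <- cohort_dims(cohort)
  stopifnot(dm$l == dm$n, setequal(perm, seq_len(dm$n)))
  longitudinal_cohort(
    histories = cohort$histories[perm],
    last_records = cohort$last_records[, perm, drop = FALSE],
    modality_slices = cohort$modality_slices,
    snp_matrix = cohort$snp_matrix[, perm, drop = FALSE],
    snp_groups = cohort$snp_groups,
    labels = cohort$labels[, perm, drop = FALSE],
    ids = cohort$ids[perm]
  )
}

# hide the labels of participants after the first l
truncate_labels <- function(cohort, l) {
  cohort$labels <- cohort$labels[, seq_len(l), drop = FALSE]
  cohort
}

#' Run the full enrichment-vs-original prediction experiment
#'
#' The protocol of the model's evaluation: split the cohort into training
#' and test participants, fit the enrichment transductively (imaging and SNP
#' features of all participants are visible, clinical scores of the training
#' participants only), enrich every last record, then predict the held-out
#' test scores with a cross-validated downstream regressor from (a) the
#' enriched representation and (b) the original last-visit representation,
#' and report per-score test RMSEs and the percent error reduction.
#'
#' @param cohort a fully labeled `longitudinal_cohort` (`l = n`), e.g. from
#'   [simulate_cohort()] with `l = n`.
#' @param hp an [hyperparams()] object for the enrichment fit.
#' @param split training fraction (default 0.8).
#' @param cv_folds folds of the downstream hyperparameter search.
#' @param model downstream model, `"ridge"` or `"svr"`.
#' @param seed seed controlling the split, fit initialization and CV folds.
#' @param allow_nonconverged keep going when the solver stops early.
#' @return list of class `enrich_experiment` with `rmse_enriched`,
#'   `rmse_original`, `pct_reduction`, the fitted model, predictions, the
#'   split indices (in input order) and a provenance block.
#' @export
run_experiment <- function(cohort, hp = hyperparams(), split = 0.8,
                           cv_folds = 5L, model = "ridge", seed = 1L,
                           allow_nonconverged = TRUE) {
  stopifnot(split > 0, split < 1)
  dm <- cohort_dims(cohort)
  if (dm$l != dm$n) {
    stop("run_experiment needs a fully labeled cohort; labels are hidden by the split itself")
  }
  n_train <- max(1L, round(split * dm$n))
  if (n_train >= dm$n) n_train <- dm$n - 1L
  perm <- with_seed(seed, sample.int(dm$n))
  train_idx <- perm[seq_len(n_train)]
  test_idx <- perm[(n_train + 1):dm$n]

  full <- reorder_cohort(cohort, perm)
  y_test <- full$labels[, (n_train + 1):dm$n, drop = FALSE]
  fit_cohort <- truncate_labels(full, n_train)

  hp$seed <- seed
  fit <- fit_enrichment(fit_cohort, hp)
  if (!fit$converged && !allow_nonconverged) {
    stop("enrichment solver did not converge; pass allow_nonconverged = TRUE to proceed")
  }

  # original features are z-scored (heterogeneous scales); the enriched
  # coordinates come from orthonormal projections of standardized data and
  # are already commensurate, so they are centered only -- rescaling them
  # would inflate low-variance projection directions
  zs <- function(M) {
    s <- apply(M, 1, stats::sd); s[s < 1e-12] <- 1
    (M - rowMeans(M)) / s
  }
  Z <- fit$Z - rowMeans(fit$Z)
  X <- zs(full$last_records)
  tr <- seq_len(n_train); te <- (n_train + 1):dm$n
  y_train <- full$labels[, tr, drop = FALSE]

  enr <- evaluate_downstream(Z[, tr, drop = FALSE], y_train,
                             Z[, te, drop = FALSE], y_test,
                             model = model, cv_folds = cv_folds, seed = seed)
  orig <- evaluate_downstream(X[, tr, drop = FALSE], y_train,
                              X[, te, drop = FALSE], y_test,
                              model = model, cv_folds = cv_folds, seed = seed)

  structure(
    list(
      rmse_enriched = enr$rmse,
      rmse_original = orig$rmse,
      pct_reduction = 100 * (orig$rmse - enr$rmse) / orig$rmse,
      downstream = list(enriched = enr, original = orig),
      fit = fit,
      split = list(train = sort(train_idx), test = sort(test_idx)),
      y_test = y_test,
      provenance = list(
        seed = seed, split = split, cv_folds = cv_folds, model = model,
        hp = unclass(hp),
        package_version = as.character(utils::packageVersion("longenrich")),
        r_version = R.version.string
      )
    ),
    class = "enrich_experiment"
  )
}

#' @export
print.enrich_experiment <- function(x, ...) {
  cat("Enrichment prediction experiment\n")
  cat(sprintf("  train/test     : %d / %d participants\n",
              length(x$split$train), length(x$split$test)))
  for (s in seq_along(x$rmse_enriched)) {
    cat(sprintf("  %-8s RMSE original %.4f | enriched %.4f (%+.1f%%)\n",
                names(x$rmse_enriched)[s], x$rmse_original[s],
                x$rmse_enriched[s], -x$pct_reduction[s]))
  }
  invisible(x)
}

#' Randomized hyperparameter search with incumbent retention
#'
#' At the first step every hyperparameter is drawn uniformly from its grid;
#' at every later step each hyperparameter independently keeps the
#' incumbent-best value with probability 1/2 and is otherwise resampled.
#' The configuration with the lowest objective wins.  Deterministic given
#' the seed.
#'
#' @param grids named list of candidate-value vectors.
#' @param budget number of evaluations (>= 1).
#' @param seed integer seed.
#' @param objective_fn function taking a named list of values, returning a
#'   scalar to minimize.
#' @return list with `best` (named list), `value`, and `history`
#'   (data.frame of evaluated configurations and objectives).
#' @export
random_search <- function(grids, budget, seed, objective_fn) {
  stopifnot(length(grids) >= 1L, budget >= 1L, all(lengths(grids) >= 1L))
  with_seed(seed, {
    draw <- function() lapply(grids, function(g) g[[sample.int(length(g), 1)]])
    best <- NULL; best_val <- Inf
    hist <- vector("list", budget)
    for (b in seq_len(budget)) {
      cand <- if (b == 1L) {
        draw()
      } else {
        fresh <- draw()
        keep <- stats::runif(length(grids)) < 0.5
        out <- fresh
        out[keep] <- best[keep]
        out
      }
      val <- objective_fn(cand)
      hist[[b]] <- c(cand, objective = val)
      if (val < best_val) {
        best <- cand; best_val <- val
      }
    }
    list(best = best, value = best_val,
         history = do.call(rbind, lapply(hist, as.data.frame)))
  })
}
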