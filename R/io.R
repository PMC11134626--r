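#' Write a cohort to its on-disk manifest format
#'
#' The format is plain text: a JSON manifest naming four CSV/TSV files plus
#' the modality map.  `visits.csv` holds one row per visit with columns
#' `participant_id`, `visit_index`, then the `d` feature columns; the visit
#' with the highest index per participant is that participant's last record.
#' `snp.csv` is `d_SNP` rows by `n` participant columns with a leading
#' `snp_id` column; `groups.tsv` maps `snp_id` to `group_id`; `labels.csv`
#' has one row per clinical score and one column per labeled participant.
#'
#' @param cohort a `longitudinal_cohort`.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dm <- cohort_dims(cohort)
  feat_names <- paste0("f", seq_len(dm$d))

  rows <- vector("list", dm$n)
  for (i in seq_len(dm$n)) {
    Xi <- cbind(cohort$histories[[i]], cohort$last_records[, i])
    df <- as.data.frame(t(Xi))
    names(df) <- feat_names
    rows[[i]] <- cbind(
      data.frame(participant_id = cohort$ids[i],
                 visit_index = seq_len(ncol(Xi))),
      df
    )
  }
  visits <- do.call(rbind, rows)
  utils::write.csv(visits, file.path(dir, "visits.csv"), row.names = FALSE)

  snp_ids <- paste0("snp", seq_len(dm$d_snp))
  snp <- data.frame(snp_id = snp_ids, cohort$snp_matrix)
  names(snp) <- c("snp_id", cohort$ids)
  utils::write.csv(snp, file.path(dir, "snp.csv"), row.names = FALSE)

  group_of <- integer(dm$d_snp)
  for (k in seq_along(cohort$snp_groups)) group_of[cohort$snp_groups[[k]]] <- k
  utils::write.table(
    data.frame(snp_id = snp_ids, group_id = paste0("g", group_of)),
    file.path(dir, "groups.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )

  lab <- data.frame(score_id = paste0("score", seq_len(dm$c)),
                    cohort$labels)
  names(lab) <- c("score_id", cohort$ids[seq_len(dm$l)])
  utils::write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE)

  manifest <- list(
    visits = "visits.csv", snp = "snp.csv", groups = "groups.tsv",
    labels = "labels.csv",
    modalities = lapply(cohort$modality_slices,
                        function(s) c(min(s), max(s)))
  )
  path <- file.path(dir, "cohort.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort from a manifest
#'
#' Participant order is taken from first appearance in `visits.csv`; labeled
#' participants (those appearing as columns of `labels.csv`) are then moved
#' to the front, as the model requires, and the permutation back to input
#' order is stored in `attr(cohort, "input_order")` so downstream reports can
#' restore it.
#'
#' @param manifest path to the JSON manifest written by [write_cohort()].
#' @return a `longitudinal_cohort`.
#' @export
read_cohort <- function(manifest) {
  dir <- dirname(manifest)
  mf <- jsonlite::read_json(manifest, simplifyVector = TRUE)

  visits <- utils::read.csv(file.path(dir, mf$visits), check.names = FALSE,
                            colClasses = c(participant_id = "character"))
  ids <- unique(visits$participant_id)
  feat_names <- setdiff(names(visits), c("participant_id", "visit_index"))

  lab_raw <- utils::read.csv(file.path(dir, mf$labels), check.names = FALSE,
                             colClasses = c(score_id = "character"))
  labeled_ids <- setdiff(names(lab_raw), "score_id")
  if (!all(labeled_ids %in% ids)) {
    stop("labels.csv names participants absent from visits.csv")
  }
  # labeled first, each block in visits.csv order
  ids_ord <- c(ids[ids %in% labeled_ids], ids[!ids %in% labeled_ids])

  histories <- vector("list", length(ids_ord))
  last_records <- matrix(0, length(feat_names), length(ids_ord))
  for (i in seq_along(ids_ord)) {
    vi <- visits[visits$participant_id == ids_ord[i], , drop = FALSE]
    vi <- vi[order(vi$visit_index), , drop = FALSE]
    if (nrow(vi) < 2L) {
      stop(sprintf("participant %s has %d visit(s); at least 2 are required",
                   ids_ord[i], nrow(vi)))
    }
    M <- t(as.matrix(vi[, feat_names, drop = FALSE]))
    histories[[i]] <- M[, -ncol(M), drop = FALSE]
    last_records[, i] <- M[, ncol(M)]
  }

  snp <- utils::read.csv(file.path(dir, mf$snp), check.names = FALSE,
                         colClasses = c(snp_id = "character"))
  snp_ids <- snp$snp_id
  snp_matrix <- as.matrix(snp[, ids_ord, drop = FALSE])
  rownames(snp_matrix) <- NULL

  grp <- utils::read.table(file.path(dir, mf$groups), sep = "\t",
                           header = TRUE, colClasses = "character")
  gid <- grp$group_id[match(snp_ids, grp$snp_id)]
  if (anyNA(gid)) stop("groups.tsv does not cover every snp_id in snp.csv")
  snp_groups <- split(seq_along(snp_ids), factor(gid, levels = unique(gid)))
  snp_groups <- lapply(snp_groups, as.integer)

  labels <- as.matrix(lab_raw[, ids_ord[seq_along(labeled_ids)], drop = FALSE])
  rownames(labels) <- lab_raw$score_id

  modality_slices <- lapply(mf$modalities, function(r) seq(r[[1]], r[[2]]))

  cohort <- longitudinal_cohort(
    histories = histories, last_records = last_records,
    modality_slices = modality_slices, snp_matrix = snp_matrix,
    snp_groups = snp_groups, labels = labels, ids = ids_ord
  )
  attr(cohort, "input_order") <- match(ids, ids_ord)
  cohort
}
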