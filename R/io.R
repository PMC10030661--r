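# Plain-text serialization of cohorts, segments, features, fold
# assignments and evaluation reports.

#' Write a cohort to a columnar sample table with a JSON sidecar
#'
#' One row per sample (`subject_id`, `record_id`, `t`, `ppg`, `abp`) in CSV,
#' plus `<stem>.json` echoing the sampling rate, units, generating spec and
#' seed.
#'
#' @param records List of `bp_record`s.
#' @param stem Output path stem (writes `<stem>.csv` and `<stem>.json`).
#' @return Invisibly, the two paths written.
#' @export
write_cohort <- function(records, stem) {
  tab <- do.call(rbind, lapply(records, function(r) {
    data.frame(subject_id = r$subject_id, record_id = r$record_id,
               t = (seq_len(r$n) - 1) / r$fs,
               ppg = r$ppg,
               abp = if (is.null(r$abp)) NA_real_ else r$abp)
  }))
  csv <- paste0(stem, ".csv")
  json <- paste0(stem, ".json")
  write.csv(tab, csv, row.names = FALSE)
  spec <- attr(records, "spec")
  sidecar <- list(
    fs = records[[1]]$fs,
    units = list(abp = "mmHg", ppg = "unit-free", t = "s"),
    n_records = length(records),
    artifacts = vapply(records, function(r) r$meta$artifact %||% NA_character_,
                       character(1)),
    seed = if (!is.null(spec)) spec$seed else NA,
    spec = if (!is.null(spec)) unclass(spec) else NULL)
  jsonlite::write_json(sidecar, json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(csv, json))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param stem Path stem used at write time.
#' @return List of `bp_record`s.
#' @export
read_cohort <- function(stem) {
  tab <- read.csv(paste0(stem, ".csv"), stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  keys <- unique(tab[, c("subject_id", "record_id")])
  recs <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- tab[tab$record_id == keys$record_id[i] &
               tab$subject_id == keys$subject_id[i], ]
    abp <- if (all(is.na(sub$abp))) NULL else sub$abp
    art <- if (!is.null(side$artifacts)) side$artifacts[i] else NA_character_
    new_bp_record(keys$subject_id[i], keys$record_id[i], side$fs,
                  sub$ppg, abp,
                  meta = list(artifact = if (is.na(art)) NA_character_ else art))
  })
  recs
}

#' Segment status table of a pipeline run
#'
#' @param result Value of [run_pipeline()].
#' @return Data frame, one row per segment: ids, labels, status, removal
#'   step and reason, artifact ground-truth tag.
#' @export
segment_table <- function(result) {
  do.call(rbind, lapply(result$segments, function(s) {
    data.frame(subject_id = s$subject_id, record_id = s$record_id,
               segment_index = s$segment_index,
               sbp = s$sbp_label, dbp = s$dbp_label,
               status = s$status, removal_step = s$removal_step,
               removal_reason = s$removal_reason,
               artifact = s$artifact, stringsAsFactors = FALSE)
  }))
}

#' Write a fold assignment as CSV + JSON summary
#'
#' @param assignment A `fold_assignment`.
#' @param stem Output path stem.
#' @return Invisibly, the paths written.
#' @export
write_fold_assignment <- function(assignment, stem) {
  csv <- paste0(stem, ".csv")
  json <- paste0(stem, ".json")
  key <- if (assignment$by == "subject") "subject_id" else "segment"
  df <- data.frame(id = names(assignment$assignment) %||%
                     seq_along(assignment$assignment),
                   fold = unname(assignment$assignment))
  names(df)[1] <- key
  write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(
    list(K = assignment$K, by = assignment$by, seed = assignment$seed,
         leakage_fraction = assignment$leakage_fraction,
         fold_class_counts = assignment$fold_class_counts),
    json, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(csv, json))
}

#' Write an evaluation report as CSV (metrics) and JSON (full)
#'
#' @param report An `evaluation_report`.
#' @param stem Output path stem.
#' @return Invisibly, the paths written.
#' @export
write_evaluation_report <- function(report, stem) {
  csv <- paste0(stem, ".csv")
  json <- paste0(stem, ".json")
  write.csv(report$metrics, csv, row.names = FALSE)
  jsonlite::write_json(
    list(metrics = report$metrics,
         comparisons = lapply(report$comparisons, function(cm) {
           list(mark = cm$mark, mase_a = cm$mase_a, mase_b = cm$mase_b)
         }),
         seed = report$config$seed,
         split_mode = report$config$split_mode, K = report$config$K),
    json, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(csv, json))
}
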