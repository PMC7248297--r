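#' Validate a longitudinal study table
#'
#' One row per scan. Required columns: `subject_id`, `group` (control /
#' training), `timepoint` (TP1 / TP2 / TP3), `tiv_mm3` (> 0). Optional
#' covariate columns `age`, `gender` (M / F), `education`, and a `path` or
#' `volume` column referencing the scan's image. Every subject must appear
#' at every time point, and (subject_id, timepoint) must be unique.
#'
#' @param df data frame of scans.
#' @param groups,timepoints allowed factor levels, in design order.
#' @return `df` with `group` and `timepoint` as factors in design order,
#'   rows sorted by (group, timepoint, subject_id).
#' @export
study_table <- function(df, groups = c("control", "training"),
                        timepoints = c("TP1", "TP2", "TP3")) {
  req <- c("subject_id", "group", "timepoint", "tiv_mm3")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("study table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(df$group %in% groups))
    stop("unknown group label(s): ",
         paste(setdiff(unique(df$group), groups), collapse = ", "),
         call. = FALSE)
  if (!all(df$timepoint %in% timepoints))
    stop("unknown timepoint label(s): ",
         paste(setdiff(unique(df$timepoint), timepoints), collapse = ", "),
         call. = FALSE)
  df$group <- factor(df$group, levels = groups)
  df$timepoint <- factor(df$timepoint, levels = timepoints)
  key <- paste(df$subject_id, df$timepoint)
  if (anyDuplicated(key))
    stop("duplicated (subject_id, timepoint) row(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  tab <- table(df$subject_id)
  incomplete <- names(tab)[tab != length(timepoints)]
  if (length(incomplete))
    stop("subject(s) missing time points: ",
         paste(incomplete, collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$tiv_mm3)) || any(df$tiv_mm3 <= 0))
    stop("tiv_mm3 must be positive and finite for every scan", call. = FALSE)
  df <- df[order(df$group, df$timepoint, df$subject_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read / write a study table as TSV
#'
#' @param path TSV file with a header row.
#' @inheritParams study_table
#' @return A validated study table (see [study_table()]).
#' @export
read_study_table <- function(path, groups = c("control", "training"),
                             timepoints = c("TP1", "TP2", "TP3")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  study_table(df, groups = groups, timepoints = timepoints)
}

#' @rdname read_study_table
#' @param df validated study table.
#' @export
write_study_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Canonical per-scan identifier used to key volume lists.
scan_id <- function(subject_id, timepoint) paste(subject_id, timepoint, sep = "_")
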