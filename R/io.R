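#' Write a simulated scan to plain-text files
#'
#' The time series goes to `<subject>_<session>_bold.tsv` (T rows x R
#' columns, header = ROI labels), the motion trace to
#' `<subject>_<session>_motion.tsv` (6 columns) and the WM/CSF traces to
#' `<subject>_<session>_nuisance.tsv`.
#'
#' @param scan a `sim_scan`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_scan_tsv <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, paste(scan$subject_id, scan$session, sep = "_"))
  ts <- scan$timeseries
  colnames(ts) <- sprintf("ROI%03d", seq_len(ncol(ts)))
  paths <- c(bold = paste0(stem, "_bold.tsv"),
             motion = paste0(stem, "_motion.tsv"),
             nuisance = paste0(stem, "_nuisance.tsv"))
  utils::write.table(ts, paths["bold"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  motion <- scan$motion
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  utils::write.table(motion, paths["motion"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(scan$nuisance, paths["nuisance"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read a scan written by [write_scan_tsv()]
#'
#' @param dir directory holding the TSV files.
#' @param subject_id,session identifiers forming the file stem.
#' @param tr_seconds repetition time to attach (not stored in the TSVs).
#' @return a `sim_scan`.
#' @export
read_scan_tsv <- function(dir, subject_id, session, tr_seconds = 2) {
  stem <- file.path(dir, paste(subject_id, session, sep = "_"))
  ts <- as.matrix(utils::read.delim(paste0(stem, "_bold.tsv")))
  motion <- as.matrix(utils::read.delim(paste0(stem, "_motion.tsv")))
  nuis <- as.matrix(utils::read.delim(paste0(stem, "_nuisance.tsv")))
  structure(list(subject_id = subject_id, session = session,
                 timeseries = unname(ts), motion = unname(motion),
                 nuisance = nuis, tr_seconds = tr_seconds),
            class = "sim_scan")
}

#' Write a cohort phenotype table as CSV
#'
#' Column dictionary: `subject_id`; `group` (HC/ROP); `sex` (F/M); `age`
#' (years); `premorbid_iq`; `subgroup` (maintainer/improver/none); `shift`
#' (planted normalization fraction, 0 for HC and diagnostic subjects);
#' `learning_score` and `<domain>_T0`/`<domain>_FU` when behavioral
#' outcomes were simulated.
#'
#' @param cohort cohort data.frame.
#' @param path output CSV path.
#' @export
write_cohort_csv <- function(cohort, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort phenotype CSV
#'
#' @param path CSV path written by [write_cohort_csv()].
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(out$group)) out$group <- factor(out$group, levels = c("HC", "ROP"))
  if (!is.null(out$sex)) out$sex <- factor(out$sex, levels = c("F", "M"))
  if (!is.null(out$subgroup))
    out$subgroup <- factor(out$subgroup,
                           levels = c("maintainer", "improver", "none"))
  out
}

#' Write a subjects-by-edges feature matrix as CSV
#'
#' First column `scan_id` (subject.session), remaining columns `edge_1` ...
#' `edge_P` in the canonical row-major upper-triangle order.
#'
#' @param features numeric matrix with rownames.
#' @param path output CSV path.
#' @export
write_feature_matrix_csv <- function(features, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(scan_id = rownames(features), features,
                   check.names = FALSE)
  colnames(df) <- c("scan_id", sprintf("edge_%d", seq_len(ncol(features))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix CSV written by [write_feature_matrix_csv()]
#'
#' @param path CSV path.
#' @return numeric matrix with scan ids as rownames.
#' @export
read_feature_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write per-subject decision records as CSV
#'
#' @param records output of [decision_records()].
#' @param path output CSV path.
#' @export
write_decisions_csv <- function(records, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a simulation configuration as YAML
#'
#' Plain hierarchical text representation of the [cohort_config()] /
#' [intervention_config()] lists (requires the `yaml` package).
#'
#' @param config config list.
#' @param path YAML path.
#' @export
write_sim_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for config files")
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for config files")
  yaml::read_yaml(path)
}

#' Write one connectivity vector as a per-scan edge CSV
#'
#' Columns: `edge_id`, `roi_i`, `roi_j`, `r`, in the canonical row-major
#' upper-triangle order.
#'
#' @param cv a `connectivity_vector` from [preprocess_scan()].
#' @param path output CSV path.
#' @export
write_connectivity_csv <- function(cv, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(edge_id = cv$edge_index$edge,
                              roi_i = cv$edge_index$i,
                              roi_j = cv$edge_index$j,
                              r = as.numeric(cv$values)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a per-scan edge CSV written by [write_connectivity_csv()]
#'
#' @param path CSV path.
#' @return data.frame with edge_id, roi_i, roi_j, r.
#' @export
read_connectivity_csv <- function(path) {
  utils::read.csv(path)
}
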