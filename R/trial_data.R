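#' Construct a trial dataset
#'
#' A `trial_dataset` bundles one row per randomized subject with the common
#' administrative data-cut day `D`. Times are measured in integer days:
#' randomization day `R` counts from study start, while the observed time
#' `T_obs`, the disposition days and the individual censoring horizon
#' `C = D - R + 1` count from randomization.
#'
#' Required subject columns:
#' \describe{
#'   \item{id}{unique subject identifier (character or integer).}
#'   \item{trt}{arm indicator, 0 = placebo, 1 = active.}
#'   \item{R}{randomization day from study start, `>= 0`.}
#'   \item{T_obs}{observed time to first event or censoring, days from
#'     randomization, `> 0`.}
#'   \item{E}{event indicator, 1 = event, 0 = censored.}
#'   \item{trt_disc_day}{day of treatment discontinuation (`NA` if never
#'     off treatment).}
#'   \item{study_disc_day}{day of study discontinuation (`NA` if followed
#'     to the data-cut).}
#'   \item{death_day}{day of death from a vital-status search (`NA` if
#'     unknown/alive).}
#' }
#' Baseline covariate columns are named via `covariates` and may be empty.
#'
#' @param subjects data.frame of subject records.
#' @param D common data-cut day (integer, days from study start).
#' @param covariates character vector naming baseline covariate columns.
#' @param validate run row-level invariant checks (default `TRUE`).
#' @return An object of class `trial_dataset`: a list with elements
#'   `subjects` (data.frame including the derived horizon column `C`),
#'   `D` and `covariates`.
#' @export
trial_dataset <- function(subjects, D, covariates = character(), validate = TRUE) {
  stopifnot(is.data.frame(subjects), length(D) == 1, is.finite(D))
  required <- c("id", "trt", "R", "T_obs", "E")
  missing_cols <- setdiff(required, names(subjects))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("trt_disc_day", "study_disc_day", "death_day")) {
    if (!col %in% names(subjects)) {
      subjects[[col]] <- rep(NA_real_, nrow(subjects))
    }
  }
  missing_cov <- setdiff(covariates, names(subjects))
  if (length(missing_cov)) {
    stop("covariate column(s) not found: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  obj <- structure(list(subjects = subjects, D = as.numeric(D),
                        covariates = covariates),
                   class = "trial_dataset")
  obj <- derive_horizons(obj)
  if (validate) validate_trial(obj)
  obj
}

#' Derive per-subject administrative horizons
#'
#' Sets the individual censoring horizon `C = D - R + 1` (days from
#' randomization) for every subject. Idempotent.
#'
#' @param data a `trial_dataset`.
#' @return The dataset with a refreshed `C` column.
#' @export
derive_horizons <- function(data) {
  stopifnot(inherits(data, "trial_dataset"))
  s <- data$subjects
  if (nrow(s) && any(s$R > data$D)) {
    bad <- which(s$R > data$D)
    stop("subject(s) randomized after the data-cut (R > D) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  data$subjects$C <- data$D - s$R + 1
  data
}

#' Validate trial dataset invariants
#'
#' Checks, row by row: `T_obs <= C`, `T_obs > 0`, `E` and `trt` binary,
#' unique ids, `trt_disc_day <= T_obs` when present, and the censored-at-
#' dropout convention (`E = 0` with `study_disc_day < C` implies
#' `T_obs == study_disc_day`). All violations are reported together with
#' their row indices.
#'
#' @param data a `trial_dataset`.
#' @return `data`, invisibly, if valid; otherwise an error.
#' @export
validate_trial <- function(data) {
  stopifnot(inherits(data, "trial_dataset"))
  s <- data$subjects
  probs <- character(0)
  flag <- function(bad, msg) {
    if (any(bad, na.rm = TRUE)) {
      rows <- which(bad)
      probs <<- c(probs, sprintf("%s at row(s) %s", msg,
                                 paste(utils::head(rows, 5), collapse = ", ")))
    }
  }
  if (anyDuplicated(s$id)) probs <- c(probs, "duplicated subject ids")
  flag(!s$trt %in% c(0, 1), "trt not in {0,1}")
  flag(!s$E %in% c(0, 1), "E not in {0,1}")
  flag(!is.finite(s$T_obs) | s$T_obs <= 0, "T_obs not a positive number")
  flag(s$R < 0, "negative randomization day")
  flag(s$T_obs > s$C + 1e-8, "T_obs exceeds horizon C")
  flag(!is.na(s$trt_disc_day) & s$trt_disc_day > s$T_obs + 1e-8,
       "trt_disc_day after observed time")
  flag(s$E == 0 & !is.na(s$study_disc_day) & s$study_disc_day < s$C &
         abs(s$T_obs - s$study_disc_day) > 1e-8,
       "censored dropout with T_obs != study_disc_day")
  if (length(probs)) {
    stop("invalid trial data: ", paste(probs, collapse = "; "), call. = FALSE)
  }
  invisible(data)
}

#' Partition subjects into completers, retrieved dropouts and missing data
#'
#' Disposition drives the whole analysis:
#' \itemize{
#'   \item \emph{missing}: study discontinuation before the administrative
#'     horizon with no prior event and no death-based completion of
#'     follow-up — the subjects whose outcome gets imputed;
#'   \item \emph{retrieved dropouts (RDs)}: subjects off randomized
#'     treatment but followed to event, death or the data-cut — the
#'     imputation basis (events after treatment discontinuation stay RDs);
#'   \item \emph{completers}: on treatment through their event or the
#'     data-cut, or followed to death.
#' }
#' The three sets are disjoint and cover the randomized population. A
#' subject whose study discontinuation falls on or after `C` is followed
#' to the cut and therefore not missing.
#'
#' @param data a `trial_dataset`.
#' @return Object of class `disposition_partition`: list of id vectors
#'   `completers`, `retrieved_dropouts`, `missing`.
#' @export
classify_disposition <- function(data) {
  stopifnot(inherits(data, "trial_dataset"))
  s <- data$subjects
  is_missing <- s$E == 0 &
    !is.na(s$study_disc_day) & s$study_disc_day < s$C &
    is.na(s$death_day)
  is_rd <- !is_missing & !is.na(s$trt_disc_day)
  part <- structure(list(
    completers = s$id[!is_missing & !is_rd],
    retrieved_dropouts = s$id[is_rd],
    missing = s$id[is_missing]
  ), class = "disposition_partition")
  stopifnot(sum(lengths(part)) == nrow(s))
  part
}

#' @export
print.disposition_partition <- function(x, ...) {
  cat("Disposition partition\n")
  cat(sprintf("  completers:         %d\n", length(x$completers)))
  cat(sprintf("  retrieved dropouts: %d\n", length(x$retrieved_dropouts)))
  cat(sprintf("  missing data:       %d\n", length(x$missing)))
  invisible(x)
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("trial_dataset: %d subjects, data-cut day %s\n",
              nrow(x$subjects), format(x$D)))
  if (length(x$covariates)) {
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a trial dataset by subject id
#'
#' @param data a `trial_dataset`.
#' @param ids subject ids to keep.
#' @return A `trial_dataset` restricted to `ids` (validation skipped; the
#'   subset of a valid dataset is valid).
#' @export
subset_trial <- function(data, ids) {
  stopifnot(inherits(data, "trial_dataset"))
  keep <- data$subjects$id %in% ids
  out <- data
  out$subjects <- data$subjects[keep, , drop = FALSE]
  rownames(out$subjects) <- NULL
  out
}

.default_dialect <- function() {
  list(id = "id", trt = "trt", R = "R", T_obs = "T_obs", E = "E",
       trt_disc_day = "trt_disc_day", study_disc_day = "study_disc_day",
       death_day = "death_day")
}

#' Read a delimited trial table
#'
#' Reads a CSV/TSV file with one row per subject. Column names in the file
#' are mapped to the canonical schema through `dialect`, a named list
#' `canonical = "file_column"`, so ADaM-like exports can be ingested
#' without renaming. `D` may be given explicitly or as a constant column
#' `D` in the file.
#'
#' @param path file path.
#' @param dialect named list mapping canonical names (see
#'   [trial_dataset()]) to file column names; unlisted names map to
#'   themselves.
#' @param D common data-cut day; required unless the file has a `D` column.
#' @param covariates character vector of covariate columns (file names,
#'   mapped verbatim).
#' @param sep field separator (default `","`).
#' @return A validated `trial_dataset`.
#' @export
read_trial_table <- function(path, dialect = NULL, D = NULL,
                             covariates = character(), sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  map <- utils::modifyList(.default_dialect(), as.list(dialect %||% list()))
  required <- c("id", "trt", "R", "T_obs", "E")
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in names(map)) {
    src <- map[[canon]]
    if (src %in% names(raw)) {
      out[[canon]] <- raw[[src]]
    } else if (canon %in% required) {
      stop("required column '", src, "' (-> ", canon, ") not found in ",
           path, call. = FALSE)
    }
  }
  for (col in c("trt", "R", "T_obs", "E", "trt_disc_day", "study_disc_day",
                "death_day")) {
    if (col %in% names(out) && !is.double(out[[col]])) {
      conv <- suppressWarnings(as.numeric(out[[col]]))
      bad <- which(!is.na(out[[col]]) & out[[col]] != "" & is.na(conv))
      if (length(bad)) {
        stop("non-numeric value in column '", col, "' at row(s): ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
      }
      out[[col]] <- conv
    }
  }
  for (cv in covariates) {
    if (!cv %in% names(raw)) {
      stop("covariate column '", cv, "' not found in ", path, call. = FALSE)
    }
    out[[cv]] <- raw[[cv]]
  }
  if (is.null(D)) {
    if (!"D" %in% names(raw)) {
      stop("data-cut day D must be supplied or present as a 'D' column",
           call. = FALSE)
    }
    D <- unique(raw$D)
    if (length(D) != 1) stop("column 'D' is not constant", call. = FALSE)
  }
  trial_dataset(out, D = D, covariates = covariates)
}

#' Write a trial dataset as delimited text
#'
#' Inverse of [read_trial_table()] (canonical column names, `D` as a
#' constant column); `read_trial_table(write_trial_table(x))` round-trips
#' every field.
#'
#' @param data a `trial_dataset`.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(data, path, sep = ",") {
  stopifnot(inherits(data, "trial_dataset"))
  out <- data$subjects
  out$C <- NULL
  out$D <- data$D
  # 17 significant digits round-trip doubles exactly
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                           sprintf("%.17g", out[[col]]))
    }
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
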