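#' Read and write beta-value matrices and CpG annotation tables
#'
#' The beta matrix travels as a delimited table with samples in rows (first
#' column `sample_id`) and CpGs in columns; the annotation as a CSV with
#' columns `cpg_id`, `chrom`, `pos` (0-based) and any profile columns.
#'
#' @param beta Samples x CpGs numeric matrix with dimnames.
#' @param path File path.
#' @return `read_beta_matrix` returns the matrix; writers return the path
#'   invisibly.
#' @name beta_io
NULL

#' @rdname beta_io
#' @export
write_beta_matrix <- function(beta, path) {
  df <- data.frame(sample_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname beta_io
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  storage.mode(m) <- "double"
  m
}

#' @rdname beta_io
#' @param profiles A CpG annotation / reference-profile data frame.
#' @export
write_cpg_table <- function(profiles, path) {
  utils::write.csv(as.data.frame(profiles), path, row.names = FALSE)
  invisible(path)
}

#' @rdname beta_io
#' @export
read_cpg_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cpg_id", "chrom", "pos")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("CpG table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (all(c("epithelial_mean", "immune_mean") %in% names(df))) {
    class(df) <- c("wq_reference_profiles", "data.frame")
  }
  df
}

#' Read a sample sheet CSV
#'
#' Validates the cohort metadata contract: `sample_id` (unique) and
#' `group` (`case` / `control`) are required; `age`, `menopausal_status`,
#' `stage`, `grade`, `histology`, `collection`, `months_to_event` and any
#' comparator columns (`ultrasound_mm`, `n_mutations`) are picked up when
#' present; unknown columns are preserved as opaque covariates.
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("sample_id", "group")) {
    if (!col %in% names(df)) {
      stop("sample sheet missing required column: ", col)
    }
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "))
  }
  if (!all(df$group %in% c("case", "control"))) {
    stop("group must be 'case' or 'control'")
  }
  if ("months_to_event" %in% names(df)) {
    bad <- !is.na(df$months_to_event) & df$months_to_event < 0
    if (any(bad)) stop("months_to_event must be non-negative")
  }
  df
}

#' Write a sample sheet CSV
#' @param meta Cohort metadata data frame.
#' @param path CSV path.
#' @export
write_sample_sheet <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a qPCR plate CSV
#'
#' Expects columns `sample_id`, `assay_id`, `replicate`, `ct`,
#' `is_calibrator`. The string `"Undetermined"` (any capitalisation) in
#' `ct` parses to the undetermined sentinel (`NA`); numeric Cts must be
#' positive.
#'
#' @param path CSV path.
#' @return A `wq_qpcr_plate` data frame.
#' @export
read_qpcr_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(ct = "character"))
  required <- c("sample_id", "assay_id", "replicate", "ct", "is_calibrator")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("qPCR CSV missing column(s): ", paste(missing, collapse = ", "))
  }
  ct_raw <- trimws(df$ct)
  undet <- tolower(ct_raw) == "undetermined"
  ct <- suppressWarnings(as.numeric(ct_raw))
  bad <- which(!undet & is.na(ct))
  if (length(bad) > 0) {
    stop("malformed Ct value in row ", bad[1], ": '", ct_raw[bad[1]], "'")
  }
  neg <- which(!undet & ct <= 0)
  if (length(neg) > 0) {
    stop("non-positive Ct value in row ", neg[1], ": ", ct[neg[1]])
  }
  ct[undet] <- NA_real_
  out <- data.frame(sample_id = df$sample_id, assay_id = df$assay_id,
                    replicate = as.integer(df$replicate), ct = ct,
                    is_calibrator = as.integer(df$is_calibrator),
                    stringsAsFactors = FALSE)
  class(out) <- c("wq_qpcr_plate", "data.frame")
  out
}

#' Write a qPCR plate CSV
#'
#' Undetermined wells (`NA` Ct) are written as the string
#' `"Undetermined"`.
#'
#' @param plate A `wq_qpcr_plate` data frame.
#' @param path CSV path.
#' @export
write_qpcr_csv <- function(plate, path) {
  out <- as.data.frame(plate)
  out$ct <- ifelse(is.na(out$ct), "Undetermined",
                   format(out$ct, trim = TRUE, scientific = FALSE,
                          digits = 15))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export candidate regions as BED
#'
#' Standard 5-column BED: chrom, 0-based half-open start/end, region name,
#' and the AUC scaled to 0-1000 in the score column.
#'
#' @param regions A `wq_regions` data frame.
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  score <- ifelse(is.na(regions$auc), 0, round(regions$auc * 1000))
  bed <- data.frame(regions$chrom, regions$start, regions$end,
                    regions$region_id, score)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Persist and restore decision thresholds as JSON
#'
#' @param thresholds A `wq_thresholds` object.
#' @param path JSON path.
#' @return `read_thresholds_json` returns a `wq_thresholds` object.
#' @name thresholds_io
NULL

#' @rdname thresholds_io
#' @export
write_thresholds_json <- function(thresholds, path) {
  jsonlite::write_json(unclass(thresholds), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname thresholds_io
#' @export
read_thresholds_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$dev_operating_points <- as.data.frame(x$dev_operating_points)
  class(x) <- "wq_thresholds"
  x
}

#' Write a per-sample score table CSV
#' @param scores A `wq_score_table` data frame.
#' @param path CSV path.
#' @export
write_score_table <- function(scores, path) {
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample score table CSV
#' @param path CSV path.
#' @return A `wq_score_table` data frame.
#' @export
read_score_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "sum_pmr", "valid") %in% names(df))) {
    stop("score table missing required columns")
  }
  class(df) <- c("wq_score_table", "data.frame")
  df
}
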