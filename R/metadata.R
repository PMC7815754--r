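#' Map days post-hatching to developmental stage
#'
#' The sampling design groups the seven sampled ages into three developmental
#' stages: 12-20 dph (S1), 27-42 dph (S2) and 56-98 dph (S3). In strict mode
#' an age outside these ranges is an error; otherwise it is assigned to the
#' nearest range with a warning.
#'
#' @param dph integer vector of days post-hatching (>= 0).
#' @param strict error on out-of-range ages (default `TRUE`).
#' @return Character vector of stages `"S1"`, `"S2"`, `"S3"`.
#' @examples
#' stage_from_dph(c(12, 42, 98))
#' @export
stage_from_dph <- function(dph, strict = TRUE) {
  if (any(!is.finite(dph)) || any(dph < 0)) stop("dph must be non-negative")
  lo <- c(S1 = 12, S2 = 27, S3 = 56)
  hi <- c(S1 = 20, S2 = 42, S3 = 98)
  stage <- rep(NA_character_, length(dph))
  for (s in names(lo)) stage[dph >= lo[s] & dph <= hi[s]] <- s
  if (anyNA(stage)) {
    if (strict) stop("dph outside the sampled stage ranges: ",
                     paste(dph[is.na(stage)], collapse = ", "))
    for (i in which(is.na(stage))) {
      gap <- pmin(abs(dph[i] - lo), abs(dph[i] - hi))
      stage[i] <- names(which.min(gap))
    }
    warning("dph outside stage ranges assigned to nearest stage")
  }
  stage
}

#' Validate per-sample metadata
#'
#' Checks the structural invariants of the study design: required columns,
#' habitat levels, stage consistent with dph, the transition flag equal to
#' `hatch_env != rear_env` for gut samples, and no cage assignment for water
#' samples.
#'
#' @param metadata a data frame with columns `sample_id`, `habitat`, `tank`,
#'   `cage`, `hatch_env`, `rear_env`, `dph`, `stage`, `transition`, `food`.
#' @return The metadata as a [tibble::tibble()], invisibly classed.
#' @export
validate_metadata <- function(metadata) {
  metadata <- tibble::as_tibble(metadata)
  req <- c("sample_id", "habitat", "tank", "cage", "hatch_env", "rear_env",
           "dph", "stage", "transition", "food")
  miss <- setdiff(req, names(metadata))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id)) stop("duplicate sample_id in metadata")
  if (!all(metadata$habitat %in% c("water", "gut")))
    stop("habitat must be 'water' or 'gut'")
  bad_env <- function(x) !(is.na(x) | x %in% c("A", "B", "C"))
  if (any(bad_env(metadata$hatch_env)) || any(bad_env(metadata$rear_env)))
    stop("hatch_env/rear_env must be A, B or C")
  if (!all(metadata$stage == stage_from_dph(metadata$dph)))
    stop("stage inconsistent with dph for sample(s): ",
         paste(metadata$sample_id[metadata$stage != stage_from_dph(metadata$dph)],
               collapse = ", "))
  gut <- metadata$habitat == "gut"
  tr <- metadata$hatch_env[gut] != metadata$rear_env[gut]
  if (any(metadata$transition[gut] != tr))
    stop("transition flag must equal hatch_env != rear_env")
  if (any(!is.na(metadata$cage[!gut])))
    stop("water samples must have no cage")
  metadata
}

#' Read sample metadata from TSV
#' @param path path to a tab-delimited metadata file.
#' @return Validated metadata tibble.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          na.strings = c("NA", ""))
  df$transition <- as.logical(df$transition)
  validate_metadata(df)
}

#' Write sample metadata as TSV
#' @param metadata validated metadata.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(as.data.frame(metadata), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
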