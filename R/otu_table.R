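#' Construct and validate an OTU table
#'
#' An OTU table is the universal community object of the package: an integer
#' matrix of read counts with OTUs as rows and samples as columns. The
#' constructor validates the invariants every downstream computation relies
#' on: unique ids, non-negative integer counts, at least one OTU and one
#' sample.
#'
#' @param counts numeric matrix, OTUs x samples, with rownames (OTU ids) and
#'   colnames (sample ids). Values must be non-negative and integer-valued.
#' @return An integer matrix of class `"otu_table"`.
#' @examples
#' tab <- otu_table(matrix(c(1, 2, 0, 3, 4, 0), nrow = 3, byrow = TRUE,
#'                         dimnames = list(c("O1", "O2", "O3"), c("s1", "s2"))))
#' colSums(tab)
#' @export
otu_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("otu_table requires OTU ids as rownames and sample ids as colnames")
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("otu_table requires at least 1 OTU and 1 sample")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate OTU ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (anyNA(counts) || any(!is.finite(counts)))
    stop("otu_table counts must be finite")
  if (any(counts < 0)) stop("otu_table counts must be non-negative")
  if (max(abs(counts - round(counts))) > 1e-8)
    stop("otu_table counts must be integer read counts")
  storage.mode(counts) <- "integer"
  class(counts) <- c("otu_table", class(counts))
  counts
}

is_otu_table <- function(x) inherits(x, "otu_table")

#' Read an OTU table from TSV or BIOM
#'
#' The TSV layout has OTUs as rows and samples as columns: a header row of
#' sample ids whose first field is `otu_id`, then one row per OTU. BIOM 2.x
#' files are read through the biomformat package when it is installed.
#'
#' @param path path to the file.
#' @param format `"tsv"` (default) or `"biom"`.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM requires the biomformat package")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
    return(otu_table(m))
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "otu_id")
    stop("malformed OTU table header at line 1: first field must be 'otu_id' ",
         "followed by sample ids")
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          row.names = 1L, comment.char = "", quote = "")
  otu_table(as.matrix(df))
}

#' Write an OTU table as TSV
#'
#' @param table an [otu_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(is_otu_table(table))
  df <- data.frame(otu_id = rownames(table), unclass(table),
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rarefy an OTU table to fixed depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) to a common depth, the standard normalisation before
#' diversity and null-model analyses. The study design this package mirrors
#' resampled all libraries to 14,666 reads, the default here. Samples with
#' fewer total reads than `depth` are dropped with a warning. Each sample's
#' draw uses an RNG stream derived from `(seed, sample_id)`, so the result
#' does not depend on column order.
#'
#' @param table an [otu_table()].
#' @param depth target reads per sample (default 14666).
#' @param seed integer seed.
#' @return A rarefied [otu_table()]; every retained column sums to `depth`.
#' @export
rarefy <- function(table, depth = 14666L, seed = 1L) {
  stopifnot(is_otu_table(table))
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1)
    stop("depth must be a positive integer")
  depth <- as.integer(depth)
  totals <- colSums(table)
  keep <- totals >= depth
  if (!any(keep)) stop("no sample reaches depth ", depth)
  if (any(!keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(colnames(table)[!keep], collapse = ", "))
  out <- matrix(0L, nrow(table), sum(keep),
                dimnames = list(rownames(table), colnames(table)[keep]))
  for (s in colnames(out)) {
    x <- table[, s]
    if (sum(x) == depth) { out[, s] <- x; next }
    cum <- cumsum(as.numeric(x))
    picks <- with_seed(derive_seed(seed, "rarefy", s),
                       sample.int(sum(x), depth, replace = FALSE))
    idx <- findInterval(picks - 0.5, cum) + 1L
    tab <- tabulate(idx, nbins = nrow(table))
    out[, s] <- as.integer(tab)
  }
  otu_table(out)
}

#' Convert counts to relative abundances
#'
#' @param table an [otu_table()].
#' @return A numeric matrix whose columns sum to 1.
#' @export
relative_abundance <- function(table) {
  stopifnot(is_otu_table(table))
  totals <- colSums(table)
  if (any(totals == 0)) stop("all-zero sample(s): ",
                             paste(colnames(table)[totals == 0], collapse = ", "))
  sweep(unclass(table), 2L, totals, "/")
}
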