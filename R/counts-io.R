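#' Read a taxon-by-sample count table
#'
#' Reads a count matrix with taxa in rows and samples in columns. The first
#' column of a TSV/CSV file must hold the taxon identifiers; all remaining
#' columns are samples. BIOM (v2.1 HDF5 or v1 JSON) files are read through the
#' \pkg{biomformat} package, with taxa on the observation axis.
#'
#' @param path Path to the input file.
#' @param format One of `"auto"` (guess from the file extension), `"tsv"`,
#'   `"csv"` or `"biom"`.
#' @return An integer matrix with taxon identifiers as row names and sample
#'   identifiers as column names. All entries are validated to be non-negative
#'   integers and identifiers to be unique; library sizes are the column sums
#'   of this matrix.
#' @seealso [trim_low_prevalence()], [read_metadata()]
#' @export
read_count_table <- function(path, format = c("auto", "tsv", "csv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("count table file not found: ", path)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", biom = "biom", "tsv")
  }
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM files requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            comment.char = "")
    if (ncol(df) < 2L) {
      stop("malformed count table '", path,
           "': need a taxon-ID column plus at least one sample column")
    }
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(!vapply(df[-1L], is.numeric, logical(1)))[1L]
      stop("malformed count table '", path, "': column '",
           colnames(df)[-1L][bad], "' is not numeric")
    }
    rownames(m) <- ids
  }
  validate_counts(m)
}

#' Validate a count matrix
#'
#' Checks that a taxon-by-sample matrix holds non-negative integral counts
#' with unique row (taxon) and column (sample) identifiers, and returns it in
#' integer storage mode.
#'
#' @param counts A numeric matrix, taxa in rows, samples in columns, with
#'   `dimnames`.
#' @return The validated matrix, storage mode integer.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix (taxa in rows, samples in columns)")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry taxon row names and sample column names")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    stop("duplicated taxon identifiers: ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- unique(colnames(counts)[duplicated(colnames(counts))])
    stop("duplicated sample identifiers: ", paste(dup, collapse = ", "))
  }
  if (anyNA(counts)) {
    stop("counts contain missing values")
  }
  if (any(counts < 0)) {
    idx <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop("negative count at taxon '", rownames(counts)[idx[1L]],
         "', sample '", colnames(counts)[idx[2L]], "'")
  }
  nonint <- abs(counts - round(counts)) > 1e-8
  if (any(nonint)) {
    idx <- which(nonint, arr.ind = TRUE)[1L, ]
    stop("non-integer count (", counts[idx[1L], idx[2L]], ") at taxon '",
         rownames(counts)[idx[1L]], "', sample '",
         colnames(counts)[idx[2L]], "'")
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Read per-sample metadata for a two-group design
#'
#' Reads a metadata table (one row per sample) and returns it aligned to the
#' samples of a count table, with the group column coded 0/1. The library size
#' is taken from a `library_size` column when present, and computed as the
#' column sums of `counts` otherwise. Library sizes always refer to the full
#' (untrimmed) table, so metadata should be built before any prevalence
#' filtering.
#'
#' @param path Path to a delimited metadata file with a header, or `NULL` to
#'   build metadata from `group` values supplied via `data`.
#' @param counts Validated count matrix (used for sample alignment and, when
#'   absent from the file, library sizes).
#' @param group_col Name of the column holding the two-level group label.
#' @param covariate_cols Character vector of additional covariate columns to
#'   retain (default none).
#' @param group_levels Optional length-2 character vector giving the explicit
#'   mapping `c(level0, level1)`; when `NULL`, sorted label order is used
#'   (first level -> 0).
#' @param sample_col Name of the sample-identifier column (default the first
#'   column).
#' @param data Optional data frame used instead of reading `path`.
#' @return A data frame with columns `sample_id`, `group` (0/1),
#'   `library_size` and any requested covariates, in count-table sample order.
#'   The applied group mapping is stored in `attr(, "group_levels")`.
#' @export
read_metadata <- function(path = NULL, counts, group_col = "group",
                          covariate_cols = character(0), group_levels = NULL,
                          sample_col = NULL, data = NULL) {
  if (is.null(data)) {
    if (!file.exists(path)) stop("metadata file not found: ", path)
    sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
    data <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                              check.names = FALSE, stringsAsFactors = FALSE,
                              comment.char = "")
  }
  if (is.null(sample_col)) sample_col <- colnames(data)[1L]
  for (nm in c(sample_col, group_col)) {
    if (!nm %in% colnames(data)) {
      stop("metadata lacks required column '", nm, "'")
    }
  }
  missing_cov <- setdiff(covariate_cols, colnames(data))
  if (length(missing_cov)) {
    stop("metadata lacks covariate column(s): ",
         paste(missing_cov, collapse = ", "))
  }
  ids <- as.character(data[[sample_col]])
  if (anyDuplicated(ids)) {
    stop("duplicated sample identifiers in metadata: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  want <- colnames(counts)
  absent <- setdiff(want, ids)
  if (length(absent)) {
    stop("samples present in counts but missing from metadata: ",
         paste(absent, collapse = ", "))
  }
  data <- data[match(want, ids), , drop = FALSE]

  raw_group <- data[[group_col]]
  lev <- if (is.null(group_levels)) sort(unique(as.character(raw_group)))
         else group_levels
  if (length(lev) != 2L || !all(as.character(raw_group) %in% lev)) {
    stop("group column '", group_col, "' must take exactly two values; got: ",
         paste(sort(unique(as.character(raw_group))), collapse = ", "))
  }
  group <- as.integer(as.character(raw_group) == lev[2L])
  if (length(unique(group)) < 2L) {
    stop("both groups must be represented at least once")
  }

  lib <- if ("library_size" %in% colnames(data)) {
    as.numeric(data[["library_size"]])
  } else {
    as.numeric(colSums(counts))
  }
  if (any(!is.finite(lib)) || any(lib <= 0)) {
    stop("library sizes must be positive for every sample")
  }

  out <- data.frame(sample_id = want, group = group, library_size = lib,
                    stringsAsFactors = FALSE)
  for (nm in covariate_cols) out[[nm]] <- data[[nm]]
  attr(out, "group_levels") <- lev
  rownames(out) <- NULL
  out
}

#' Trim low-prevalence taxa
#'
#' Removes taxa present (count strictly greater than zero) in fewer than
#' `min_prevalence` of the samples; the default keeps taxa present in at least
#' 5% of samples. Library sizes are a property of the untrimmed table (held in
#' the sample metadata) and are not recomputed here.
#'
#' @param counts Validated count matrix.
#' @param min_prevalence Minimum fraction of samples a taxon must be present
#'   in (inclusive). Default 0.05.
#' @return The trimmed count matrix. Idempotent.
#' @export
trim_low_prevalence <- function(counts, min_prevalence = 0.05) {
  stopifnot(min_prevalence >= 0, min_prevalence <= 1)
  prev <- rowMeans(counts > 0)
  keep <- prev >= min_prevalence
  if (!any(keep)) {
    stop("prevalence trim at ", min_prevalence, " removed every taxon")
  }
  counts[keep, , drop = FALSE]
}

#' Write a differential-abundance result table
#'
#' Writes results as a tab-separated file with one row per tested taxon and
#' the columns `taxon_id, method, estimate, se, z, p, p_adj, effect_size,
#' effect_scale, converged, firth_used, rf_flag`. Numeric fields are written
#' with 15 significant digits so a read-back round trip reproduces them.
#'
#' @param results A result data frame as produced by [run_all_taxa()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0L) {
    stop("results must be a non-empty data frame")
  }
  out <- results
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) format(x, digits = 15, trim = TRUE))
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) {
    stop("could not write results to '", path, "': ", conditionMessage(e))
  })
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path Path to a results TSV.
#' @return A data frame with numeric columns restored.
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
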