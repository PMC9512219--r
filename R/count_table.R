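#' Construct a sample-by-taxon count table
#'
#' A count table is an integer matrix with samples in rows and taxa in
#' columns, carrying the original library sizes (row sums at construction
#' time) as an attribute.  Library sizes are deliberately *not* recomputed
#' when taxa are dropped later (see [filter_rare_taxa()]): relative
#' abundances are always defined as count divided by the total number of
#' reads sequenced for the sample.
#'
#' @param x A non-negative integer matrix or data frame, samples in rows,
#'   with unique row (sample) and column (taxon) names.
#' @param library_sizes Optional named vector of library sizes; defaults to
#'   the row sums of `x`.
#' @return A `count_table` object (an integer matrix with a
#'   `library_sizes` attribute).
#' @examples
#' m <- matrix(c(1L, 2L, 3L, 0L, 0L, 5L), 2, 3, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
#' ct <- count_table(m)
#' library_sizes(ct)
#' @export
count_table <- function(x, library_sizes = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop("`x` must be a matrix or data frame", call. = FALSE)
  if (!is.numeric(x)) stop("count table entries must be numeric", call. = FALSE)
  if (anyNA(x)) stop("count table contains missing values", call. = FALSE)
  if (any(x < 0)) stop("count table contains negative entries", call. = FALSE)
  if (any(abs(x - round(x)) > 1e-8)) {
    stop("count table contains non-integer entries", call. = FALSE)
  }
  if (nrow(x) < 2) stop("need at least 2 samples", call. = FALSE)
  if (ncol(x) < 1) stop("need at least 1 taxon", call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- paste0("sample", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("taxon", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("duplicate sample IDs", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicate taxon IDs", call. = FALSE)
  storage.mode(x) <- "integer"
  if (is.null(library_sizes)) {
    library_sizes <- rowSums(x)
  } else {
    if (length(library_sizes) != nrow(x)) {
      stop("`library_sizes` must have one entry per sample", call. = FALSE)
    }
    library_sizes <- as.numeric(library_sizes)
  }
  if (any(library_sizes <= 0)) {
    stop("all library sizes must be positive (empty sample?)", call. = FALSE)
  }
  names(library_sizes) <- rownames(x)
  structure(x, library_sizes = library_sizes, class = c("count_table", "matrix"))
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d samples x %d taxa\n", nrow(x), ncol(x)))
  cat(sprintf("  library sizes: median %s (range %s-%s)\n",
              format(stats::median(library_sizes(x))),
              format(min(library_sizes(x))), format(max(library_sizes(x)))))
  invisible(x)
}

#' Library sizes of a count table
#'
#' @param x A [count_table()].
#' @return Named numeric vector of per-sample library sizes as recorded at
#'   construction (i.e. before any taxon filtering).
#' @export
library_sizes <- function(x) {
  ls <- attr(x, "library_sizes")
  if (is.null(ls)) rowSums(x) else ls
}

#' Subset of `[` preserving count_table attributes for row/column selection
#' @export
#' @keywords internal
`[.count_table` <- function(x, i, j, ..., drop = FALSE) {
  ls <- library_sizes(x)
  out <- NextMethod(drop = FALSE)
  if (!missing(i)) ls <- ls[i]
  structure(out, library_sizes = ls, class = c("count_table", "matrix"))
}

#' Drop taxa observed in too few samples
#'
#' Keeps exactly the taxa with a nonzero count in at least `min_prevalence`
#' samples.  The sample set and the recorded library sizes are unchanged:
#' downstream relative abundances remain counts divided by the *original*
#' library sizes.
#'
#' @param x A [count_table()].
#' @param min_prevalence Minimum number of samples a taxon must appear in
#'   (count > 0) to be retained.  Default 5.
#' @return A filtered `count_table`.
#' @export
filter_rare_taxa <- function(x, min_prevalence = 5) {
  stopifnot(inherits(x, "count_table"))
  if (min_prevalence < 0) stop("`min_prevalence` must be >= 0", call. = FALSE)
  prevalence <- colSums(x > 0)
  keep <- prevalence >= min_prevalence
  if (!any(keep)) {
    stop("all taxa filtered out at min_prevalence = ", min_prevalence,
         call. = FALSE)
  }
  x[, keep]
}

.guess_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a count table from delimited text or BIOM v1 JSON
#'
#' @param path Path to a TSV/CSV file (first column sample or taxon IDs,
#'   header row with the other dimension's IDs) or a BIOM v1 (JSON) file.
#' @param orientation `"samples"` if samples are in rows (default) or
#'   `"taxa"` if taxa are in rows (the table is transposed on read).
#'   Ignored for BIOM input (BIOM stores taxa in rows).
#' @param delim Field delimiter; inferred from the extension when `NULL`
#'   (`.csv` is comma, anything else tab).
#' @return A [count_table()] in samples-in-rows orientation.
#' @export
read_count_table <- function(path, orientation = c("samples", "taxa"),
                             delim = NULL) {
  orientation <- match.arg(orientation)
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM files requires the biomformat package", call. = FALSE)
    }
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))  # taxa x samples
    return(count_table(t(m)))
  }
  df <- readr::read_delim(path, delim = .guess_delim(path, delim),
                          col_types = readr::cols(), progress = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in count table", call. = FALSE)
  rownames(m) <- ids
  if (orientation == "taxa") m <- t(m)
  count_table(m)
}

#' Write a count table as TSV (samples in rows)
#'
#' @param x A [count_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  df <- tibble::as_tibble(as.data.frame(unclass(x)), rownames = "sample_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read survival metadata aligned to a count table
#'
#' Reads a delimited metadata table containing a follow-up time column, an
#' event indicator column and optional covariate columns, and aligns it to a
#' given set of sample IDs (typically the rows of a count table).  Covariates
#' are expanded through [stats::model.matrix()] (so factors become dummy
#' variables) and centered to mean zero.
#'
#' @param path Path to a TSV/CSV file whose first column holds sample IDs
#'   (or `data`, a data frame, may be given directly).
#' @param time_col,event_col Names of the follow-up time and event indicator
#'   columns.  The event column may be coded 0/1, logical, or "TRUE"/"FALSE".
#' @param covariate_cols Character vector of covariate column names (may be
#'   empty).
#' @param sample_ids Optional character vector; the metadata is reordered to
#'   match, and an error lists any IDs without metadata.
#' @param data Optional data frame used instead of reading `path`.
#' @param delim Field delimiter (see [read_count_table()]).
#' @return A list with elements `sample_ids`, `time` (positive numeric),
#'   `event` (0/1 integer) and `covariates` (centered numeric matrix, zero
#'   columns when no covariates were requested).
#' @export
read_metadata <- function(path, time_col, event_col,
                          covariate_cols = character(), sample_ids = NULL,
                          data = NULL, delim = NULL) {
  if (is.null(data)) {
    data <- readr::read_delim(path, delim = .guess_delim(path, delim),
                              col_types = readr::cols(), progress = FALSE)
  }
  data <- as.data.frame(data)
  ids <- as.character(data[[1]])
  if (anyDuplicated(ids)) stop("duplicate sample IDs in metadata", call. = FALSE)
  rownames(data) <- ids
  for (col in c(time_col, event_col, covariate_cols)) {
    if (!col %in% names(data)) {
      stop("metadata column not found: ", col, call. = FALSE)
    }
  }
  if (!is.null(sample_ids)) {
    missing_ids <- setdiff(sample_ids, ids)
    if (length(missing_ids)) {
      stop("samples missing from metadata: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    data <- data[sample_ids, , drop = FALSE]
    ids <- sample_ids
  }
  time <- as.numeric(data[[time_col]])
  if (anyNA(time) || any(time <= 0)) {
    stop("follow-up times must be positive and non-missing", call. = FALSE)
  }
  event <- .coerce_event(data[[event_col]])
  if (length(covariate_cols)) {
    sub <- data[, covariate_cols, drop = FALSE]
    if (anyNA(sub)) stop("missing covariate values are not supported", call. = FALSE)
    X <- stats::model.matrix(~ . , data = sub)[, -1, drop = FALSE]
    X <- center_covariates(X)
  } else {
    X <- matrix(numeric(0), nrow = length(time), ncol = 0)
  }
  rownames(X) <- ids
  list(sample_ids = ids, time = time, event = event, covariates = X)
}

.coerce_event <- function(v) {
  if (is.logical(v)) v <- as.integer(v)
  if (is.character(v)) {
    u <- toupper(trimws(v))
    if (all(u %in% c("TRUE", "FALSE"))) v <- as.integer(u == "TRUE") else v <- suppressWarnings(as.numeric(v))
  }
  v <- as.numeric(v)
  if (anyNA(v) || !all(v %in% c(0, 1))) {
    stop("event indicator must be codable as 0/1", call. = FALSE)
  }
  as.integer(v)
}

#' Center covariate columns to mean zero
#'
#' @param X Numeric matrix (samples in rows).
#' @return Centered matrix with attribute `centered = TRUE`.  An error is
#'   raised if the centered matrix is column-rank deficient.
#' @export
center_covariates <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) == 0) return(structure(X, centered = TRUE))
  Xc <- sweep(X, 2, colMeans(X))
  if (qr(Xc)$rank < ncol(Xc)) {
    warning("covariates are rank deficient after centering")
  }
  structure(Xc, centered = TRUE)
}
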