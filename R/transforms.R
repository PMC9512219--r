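#' Convert counts to an analysis scale
#'
#' Produces the taxon data matrix analyzed by the tests: relative abundance
#' (count divided by the *original* library size), arcsin-root-transformed
#' relative abundance (`asin(sqrt(p))`, variance-stabilizing for
#' (Dirichlet-)multinomial proportions), or presence-absence (indicator of
#' count > 0).  Optionally column-centers the result, as required by the
#' linear-model machinery.
#'
#' @param counts A [count_table()].
#' @param scale One of `"relabund"`, `"arcsinroot"`, `"presence"`.
#' @param center Center each taxon column to mean zero?  Default `FALSE`.
#' @return A numeric matrix with attributes `scale` and `centered`.
#' @examples
#' ct <- count_table(matrix(c(2L, 2L, 0L, 1L, 0L, 3L), 2, 3, byrow = TRUE))
#' taxon_matrix(ct, "relabund")
#' @export
taxon_matrix <- function(counts, scale = c("relabund", "arcsinroot", "presence"),
                         center = FALSE) {
  scale <- match.arg(scale)
  stopifnot(inherits(counts, "count_table"))
  ls <- library_sizes(counts)
  if (any(ls <= 0)) stop("zero library size", call. = FALSE)
  m <- unclass(counts)
  attr(m, "library_sizes") <- NULL
  Z <- switch(scale,
    relabund = sweep(m, 1, ls, "/"),
    arcsinroot = asin(sqrt(pmin(sweep(m, 1, ls, "/"), 1))),
    presence = (m > 0) + 0
  )
  if (center) Z <- center_columns(Z)
  structure(Z, scale = scale, centered = center)
}

#' Center the columns of a matrix
#'
#' @param Z Numeric matrix.
#' @return `Z` with each column shifted to mean zero; attribute
#'   `centered = TRUE` (other attributes preserved).
#' @export
center_columns <- function(Z) {
  out <- sweep(Z, 2, colMeans(Z))
  attributes(out)[c("scale")] <- attributes(Z)[c("scale")]
  attr(out, "centered") <- TRUE
  out
}

#' Rarefy a count table to a fixed depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) to a common depth.  Samples whose library size is below
#' the depth are dropped with a warning.
#'
#' @param counts A [count_table()].
#' @param depth Target number of reads per sample (positive integer).
#' @param seed Integer seed making the subsample reproducible.
#' @return A rarefied [count_table()]; its recorded library sizes equal the
#'   rarefaction depth.
#' @export
rarefy <- function(counts, depth, seed) {
  stopifnot(inherits(counts, "count_table"))
  if (depth <= 0) stop("`depth` must be positive", call. = FALSE)
  ls <- rowSums(counts)
  keep <- ls >= depth
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) below rarefaction depth dropped")
    if (sum(keep) < 2) stop("fewer than 2 samples at this depth", call. = FALSE)
  }
  m <- unclass(counts)[keep, , drop = FALSE]
  set.seed(seed)
  J <- ncol(m)
  out <- t(apply(m, 1, function(row) {
    if (sum(row) == depth) return(as.integer(row))
    reads <- sample(rep.int(seq_len(J), row), depth)
    tabulate(reads, nbins = J)
  }))
  dimnames(out) <- dimnames(m)
  count_table(out)
}

#' Between-sample distance matrix
#'
#' Computes Bray-Curtis (on relative abundances), Jaccard (on
#' presence-absence) or Euclidean (any scale) distances between the rows of
#' a taxon matrix.  Bray-Curtis is `sum|x - y| / sum(x + y)`; Jaccard is
#' `1 - |intersection| / |union|` with two empty samples assigned distance
#' 0.  The input must be uncentered.
#'
#' @param Z A [taxon_matrix()] (uncentered) on the scale the metric expects.
#' @param metric One of `"bray-curtis"`, `"jaccard"`, `"euclidean"`.
#' @return A symmetric `n x n` matrix with zero diagonal and attribute
#'   `metric`.
#' @export
distance_matrix <- function(Z, metric = c("bray-curtis", "jaccard", "euclidean")) {
  metric <- match.arg(metric)
  if (isTRUE(attr(Z, "centered"))) {
    stop("distances are computed on uncentered data", call. = FALSE)
  }
  scale <- attr(Z, "scale")
  if (metric == "bray-curtis" && !is.null(scale) && scale != "relabund") {
    stop("Bray-Curtis requires the relative-abundance scale", call. = FALSE)
  }
  if (metric == "jaccard" && !is.null(scale) && scale != "presence") {
    stop("Jaccard requires the presence-absence scale", call. = FALSE)
  }
  # vegdist warns on all-zero rows; their pairs are set to 0 below
  D <- switch(metric,
    "bray-curtis" = as.matrix(suppressWarnings(vegan::vegdist(Z, method = "bray"))),
    "jaccard" = as.matrix(suppressWarnings(vegan::vegdist(Z, method = "jaccard"))),
    "euclidean" = as.matrix(stats::dist(Z))
  )
  D[is.na(D)] <- 0  # pairs of all-zero samples: identical by convention
  diag(D) <- 0
  rownames(D) <- colnames(D) <- rownames(Z)
  structure(D, metric = metric)
}

#' Gower-center a distance matrix into a kernel
#'
#' Double-centers the matrix of *squared* distances:
#' `K = -(1/2) C (D o D) C` with `C = I - 11'/n`.  When `D` holds Euclidean
#' distances between rows of a column-centered matrix `Z`, `K = Z Z'`
#' exactly (the linear kernel).  Squaring is applied for every metric,
#' matching the PERMANOVA / MiRKAT convention, even though Bray-Curtis is a
#' semimetric (the kernel may then have negative eigenvalues, which are
#' retained).
#'
#' @param D A [distance_matrix()] (or any symmetric matrix of distances).
#' @return An `n x n` kernel matrix whose rows sum to zero; attribute
#'   `metric` is carried over.
#' @export
gower_center <- function(D) {
  D <- as.matrix(D)
  A <- -0.5 * D * D
  rm <- rowMeans(A)
  K <- A - outer(rm, rep(1, ncol(A))) - outer(rep(1, nrow(A)), colMeans(A)) + mean(A)
  K <- (K + t(K)) / 2
  structure(K, metric = attr(D, "metric"))
}

#' Write / read a square distance matrix as TSV
#'
#' Allows externally computed distances (e.g. UniFrac from other tools) to
#' feed the distance-based tests.
#'
#' @param D Square distance matrix with sample IDs as dimnames.
#' @param path File path.
#' @return `path` (write) or the distance matrix (read).
#' @export
write_distance_matrix <- function(D, path) {
  df <- tibble::as_tibble(as.data.frame(as.matrix(D)), rownames = "sample_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (nrow(m) != ncol(m)) stop("distance matrix must be square", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix must be symmetric", call. = FALSE)
  m
}
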