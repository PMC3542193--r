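#' Construct a labeled expression dataset
#'
#' Bundles a genes-by-samples expression matrix with per-sample binary class
#' labels (0 = normal, 1 = disease). This is the currency passed between the
#' ranking, clustering and evaluation stages.
#'
#' @param matrix Numeric matrix, genes in rows, samples in columns. Must have
#'   unique, non-missing rownames (gene identifiers) and colnames (sample
#'   identifiers) and no missing entries.
#' @param labels Integer/numeric vector of 0s and 1s, one per column of
#'   `matrix` (0 = normal, 1 = disease), or a named vector matched to
#'   colnames.
#' @return An object of class `mapkl_dataset`: a list with elements `matrix`
#'   and `labels` (integer 0/1, named by sample).
#' @export
mapkl_dataset <- function(matrix, labels) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("`matrix` must be a numeric matrix (genes x samples)")
  if (anyNA(matrix))
    stop("expression matrix contains missing values; imputation is not supported")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("expression matrix must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(matrix)))
    stop("duplicate gene identifier(s): ",
         paste(unique(rownames(matrix)[duplicated(rownames(matrix))]), collapse = ", "))
  if (anyDuplicated(colnames(matrix)))
    stop("duplicate sample identifier(s): ",
         paste(unique(colnames(matrix)[duplicated(colnames(matrix))]), collapse = ", "))
  if (!is.null(names(labels))) {
    missing <- setdiff(colnames(matrix), names(labels))
    if (length(missing))
      stop("sample(s) missing from labels: ", paste(missing, collapse = ", "))
    labels <- labels[colnames(matrix)]
  }
  if (length(labels) != ncol(matrix))
    stop("length(labels) [", length(labels), "] != number of samples [",
         ncol(matrix), "]")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0 (normal) or 1 (disease)")
  structure(list(matrix = matrix, labels = setNames(labels, colnames(matrix))),
            class = "mapkl_dataset")
}

#' @export
print.mapkl_dataset <- function(x, ...) {
  cat("mapkl_dataset:", nrow(x$matrix), "genes x", ncol(x$matrix), "samples",
      sprintf("(%d normal, %d disease)\n", sum(x$labels == 0L), sum(x$labels == 1L)))
  invisible(x)
}

#' Number of genes / samples in a dataset
#' @param ds A `mapkl_dataset`.
#' @return Integer count.
#' @export
n_genes <- function(ds) nrow(ds$matrix)

#' @rdname n_genes
#' @export
n_samples <- function(ds) ncol(ds$matrix)

#' Read an expression matrix and class labels from CSV files
#'
#' The matrix file is comma-delimited with gene identifiers in the first
#' column and sample identifiers in the header row. The labels file has two
#' columns (header required): sample identifier and class token. Class tokens
#' are mapped to normal/disease through an explicit dictionary; no alphabetic
#' guessing is performed.
#'
#' @param matrix_path Path to the expression CSV (genes x samples).
#' @param labels_path Path to the labels CSV (columns: sample, class token).
#' @param label_map Named character vector or list with entries `normal` and
#'   `disease` giving the tokens used in the labels file.
#' @param transpose If `TRUE` the matrix file is samples x genes and is
#'   transposed after reading.
#' @return A [mapkl_dataset()] with columns in matrix-file order.
#' @export
read_expression_csv <- function(matrix_path, labels_path,
                                label_map = c(normal = "0", disease = "1"),
                                transpose = FALSE) {
  label_map <- unlist(label_map)
  if (!all(c("normal", "disease") %in% names(label_map)))
    stop("`label_map` must name the 'normal' and 'disease' tokens explicitly")
  dt <- data.table::fread(matrix_path, header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1))
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric cell(s) in expression matrix ", matrix_path)
  rownames(m) <- ids
  if (transpose) m <- t(m)
  lab <- data.table::fread(labels_path, header = TRUE, data.table = FALSE,
                           colClasses = "character")
  if (ncol(lab) < 2)
    stop("labels file must have two columns: sample identifier, class token")
  tokens <- setNames(as.character(lab[[2]]), as.character(lab[[1]]))
  missing <- setdiff(colnames(m), names(tokens))
  if (length(missing))
    stop("sample(s) in matrix absent from labels file: ",
         paste(missing, collapse = ", "))
  tokens <- tokens[colnames(m)]
  unknown <- setdiff(unique(tokens), unname(label_map))
  if (length(unknown))
    stop("label token(s) not covered by label_map: ",
         paste(unknown, collapse = ", "))
  labels <- ifelse(tokens == label_map[["disease"]], 1L, 0L)
  mapkl_dataset(m, setNames(labels, colnames(m)))
}

#' Write an expression matrix (and optional labels) to CSV
#'
#' Values are serialized with 15 significant digits so read/write round-trips
#' preserve them to full double precision.
#'
#' @param ds A `mapkl_dataset` or a bare numeric matrix with dimnames.
#' @param matrix_path Output path for the expression CSV.
#' @param labels_path Optional output path for a two-column labels CSV.
#' @param label_map Tokens written for normal/disease (defaults "0"/"1").
#' @return Invisibly, `matrix_path`.
#' @export
write_expression_csv <- function(ds, matrix_path, labels_path = NULL,
                                 label_map = c(normal = "0", disease = "1")) {
  m <- if (inherits(ds, "mapkl_dataset")) ds$matrix else ds
  df <- data.frame(gene_id = rownames(m),
                   signif(m, 15), check.names = FALSE)
  data.table::fwrite(df, matrix_path)
  if (!is.null(labels_path)) {
    if (!inherits(ds, "mapkl_dataset"))
      stop("labels_path given but `ds` carries no labels")
    tok <- ifelse(ds$labels == 1L, label_map[["disease"]], label_map[["normal"]])
    data.table::fwrite(data.frame(sample_id = colnames(m), class = tok),
                       labels_path)
  }
  invisible(matrix_path)
}

#' Log-transform an expression matrix with optional floor/ceiling clamping
#'
#' Implements the classic microarray preprocessing step: raw intensities are
#' optionally clamped to a floor and ceiling (e.g. the Golub convention of
#' floor 100 and ceiling 16,000) and then log-transformed in base 2 or 10.
#'
#' @param m Numeric matrix (genes x samples).
#' @param base Logarithm base, 2 or 10.
#' @param floor,ceiling Optional clamp bounds applied before the log.
#' @return Matrix of the same shape and dimnames, log-transformed.
#' @export
log_transform <- function(m, base = 2, floor = NULL, ceiling = NULL) {
  stopifnot(base %in% c(2, 10))
  if (!is.null(floor)) m <- pmax(m, floor)
  if (!is.null(ceiling)) m <- pmin(m, ceiling)
  if (any(m <= 0))
    stop("non-positive value(s) after clamping; supply a positive `floor`")
  log(m, base = base)
}

#' Quantile-normalize an expression matrix across samples
#'
#' Forces every sample (column) to share the same empirical distribution: the
#' row-wise mean of the per-column sorted values. Ties within a column receive
#' the mean of the quantile values they span. Idempotent.
#'
#' @param m Numeric matrix (genes x samples), at least 2 samples.
#' @return Quantile-normalized matrix, same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  if (ncol(m) < 2) stop("quantile normalization needs at least 2 samples")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Restrict a dataset to a subset of samples
#' @param ds A `mapkl_dataset`.
#' @param idx Column indices or sample names.
#' @return A `mapkl_dataset` with the selected samples.
#' @export
subset_samples <- function(ds, idx) {
  mapkl_dataset(ds$matrix[, idx, drop = FALSE], ds$labels[idx])
}

#' Restrict a dataset to a subset of genes (in the given order)
#' @param ds A `mapkl_dataset`.
#' @param genes Row indices or gene names.
#' @return A `mapkl_dataset` with the selected genes.
#' @export
subset_genes <- function(ds, genes) {
  if (is.character(genes)) {
    missing <- setdiff(genes, rownames(ds$matrix))
    if (length(missing))
      stop("gene(s) absent from dataset: ", paste(missing, collapse = ", "))
  }
  mapkl_dataset(ds$matrix[genes, , drop = FALSE], ds$labels)
}
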