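#' Spatial slice container
#'
#' Bundles a spots x genes count matrix with per-spot planar coordinates in
#' micrometres. Coordinates are metric and Cartesian throughout the package;
#' no pixel or array-index convention is used, because every downstream
#' alignment computation (mutual nearest neighbours, translation bounds,
#' shifting distances) is expressed in micrometres.
#'
#' @param counts numeric matrix, spots in rows, genes in columns; must be
#'   non-negative and carry unique column (gene) names. Duplicated gene names
#'   are collapsed by summation with a message.
#' @param coords numeric matrix or data frame with one row per spot and two
#'   columns (x, y) in micrometres.
#' @param slice_id character scalar identifying the slice.
#' @param z optional z position of the slice in micrometres.
#' @param domains optional integer vector of per-spot domain labels.
#' @return An object of class `slice_data`: a list with elements `counts`,
#'   `coords`, `slice_id`, `z` and optionally `domains`.
#' @export
slice_data <- function(counts, coords, slice_id = "slice", z = NA_real_,
                       domains = NULL) {
  counts <- as.matrix(counts)
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  storage.mode(coords) <- "double"
  if (nrow(counts) != nrow(coords)) {
    stop(sprintf("count matrix and coordinates disagree: %d vs %d rows",
                 nrow(counts), nrow(coords)))
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("gene", seq_len(ncol(counts)))
  }
  counts <- collapse_duplicate_genes(counts)
  colnames(coords) <- c("x", "y")
  if (!is.null(domains)) {
    domains <- as.integer(domains)
    stopifnot(length(domains) == nrow(counts))
  }
  structure(list(counts = counts, coords = coords, slice_id = slice_id,
                 z = z, domains = domains),
            class = "slice_data")
}

#' @exportS3Method base::print
print.slice_data <- function(x, ...) {
  cat(sprintf("<slice_data> '%s': %d spots x %d genes%s\n", x$slice_id,
              nrow(x$counts), ncol(x$counts),
              if (is.finite(x$z)) sprintf(", z = %g um", x$z) else ""))
  invisible(x)
}

#' Single-cell reference container
#'
#' Holds a cells x genes count matrix with one cell-type label per cell.
#' The per-type frequencies f_t (the composition of each cell type in the
#' reference) are computed on construction and drive the pseudo-spot
#' sampling probabilities. Types represented by fewer than two cells are
#' dropped with a warning: a single cell cannot support within-type
#' resampling or marker statistics.
#'
#' @param counts numeric matrix, cells x genes, non-negative.
#' @param cell_types character or factor of per-cell labels, one per row.
#' @return An object of class `sc_reference` with elements `counts`,
#'   `cell_types` (factor) and `type_freq` (named, sums to 1).
#' @export
sc_reference <- function(counts, cell_types) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(cell_types) != nrow(counts)) {
    stop("one cell-type label per cell is required")
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("gene", seq_len(ncol(counts)))
  }
  counts <- collapse_duplicate_genes(counts)
  cell_types <- factor(as.character(cell_types))
  tab <- table(cell_types)
  drop <- names(tab)[tab < 2]
  if (length(drop)) {
    warning(sprintf("dropping %d cell type(s) with < 2 cells: %s",
                    length(drop), paste(drop, collapse = ", ")))
    keep <- !(cell_types %in% drop)
    counts <- counts[keep, , drop = FALSE]
    cell_types <- droplevels(cell_types[keep])
  }
  f <- as.numeric(table(cell_types)) / length(cell_types)
  names(f) <- levels(cell_types)
  structure(list(counts = counts, cell_types = cell_types, type_freq = f),
            class = "sc_reference")
}

#' @exportS3Method base::print
print.sc_reference <- function(x, ...) {
  cat(sprintf("<sc_reference> %d cells x %d genes, %d types\n",
              nrow(x$counts), ncol(x$counts), nlevels(x$cell_types)))
  invisible(x)
}

collapse_duplicate_genes <- function(counts) {
  gn <- colnames(counts)
  if (anyDuplicated(gn)) {
    dup <- unique(gn[duplicated(gn)])
    message(sprintf("collapsing %d duplicated gene name(s) by summation",
                    length(dup)))
    counts <- t(rowsum(t(counts), group = gn, reorder = FALSE))
  }
  counts
}

#' Read one spatial slice from disk
#'
#' Reads a spots x genes matrix (dense CSV/TSV with header and row names, or
#' Matrix Market triplets with sidecar row/column name files) together with a
#' coordinate table `spot_id,x,y[,z]` and returns a validated [slice_data].
#' Spots are matched to coordinates by `spot_id` when the matrix carries row
#' names, otherwise by file order.
#'
#' @param matrix_path path to the count matrix.
#' @param coords_path path to the coordinate CSV.
#' @param fmt one of `"csv"`, `"tsv"`, `"mtx"`.
#' @param rownames_path,colnames_path sidecar files (one name per line) for
#'   `fmt = "mtx"`; default `<matrix_path>.rownames` / `.colnames`.
#' @param slice_id slice identifier; defaults to the matrix file name.
#' @return A [slice_data] object.
#' @export
load_slice <- function(matrix_path, coords_path, fmt = c("csv", "tsv", "mtx"),
                       rownames_path = NULL, colnames_path = NULL,
                       slice_id = NULL) {
  fmt <- match.arg(fmt)
  if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
  if (!file.exists(coords_path)) stop("coordinate file not found: ", coords_path)
  if (fmt == "mtx") {
    m <- as.matrix(Matrix::readMM(matrix_path))
    if (is.null(rownames_path)) rownames_path <- paste0(matrix_path, ".rownames")
    if (is.null(colnames_path)) colnames_path <- paste0(matrix_path, ".colnames")
    if (file.exists(rownames_path)) rownames(m) <- readLines(rownames_path)
    if (file.exists(colnames_path)) colnames(m) <- readLines(colnames_path)
  } else {
    sep <- if (fmt == "csv") "," else "\t"
    df <- utils::read.table(matrix_path, sep = sep, header = TRUE,
                            row.names = 1, check.names = FALSE)
    m <- as.matrix(df)
  }
  co <- utils::read.csv(coords_path, check.names = FALSE)
  need <- c("spot_id", "x", "y")
  if (!all(need %in% names(co))) {
    stop("coordinate file must have columns spot_id,x,y")
  }
  if (nrow(m) != nrow(co)) {
    stop(sprintf("matrix/coordinate row mismatch: %d vs %d", nrow(m), nrow(co)))
  }
  if (!is.null(rownames(m)) && all(co$spot_id %in% rownames(m))) {
    m <- m[match(co$spot_id, rownames(m)), , drop = FALSE]
  } else {
    rownames(m) <- co$spot_id
  }
  z <- if ("z" %in% names(co)) unique(co$z)[1] else NA_real_
  if (is.null(slice_id)) slice_id <- sub("\\.[^.]*$", "", basename(matrix_path))
  slice_data(m, as.matrix(co[, c("x", "y")]), slice_id = slice_id, z = z)
}

#' Write one slice to disk
#'
#' Inverse of [load_slice] for the dense CSV layout; `load_slice` on the
#' written files reproduces counts and coordinates exactly.
#'
#' @param slice a [slice_data] object.
#' @param matrix_path,coords_path output paths.
#' @return Invisibly, the input slice.
#' @export
write_slice <- function(slice, matrix_path, coords_path) {
  m <- slice$counts
  if (is.null(rownames(m))) rownames(m) <- paste0("spot", seq_len(nrow(m)))
  utils::write.csv(as.data.frame(m), matrix_path)
  co <- data.frame(spot_id = rownames(m),
                   x = slice$coords[, 1], y = slice$coords[, 2])
  if (is.finite(slice$z)) co$z <- slice$z
  utils::write.csv(co, coords_path, row.names = FALSE)
  invisible(slice)
}

#' Read a single-cell reference from disk
#'
#' @param matrix_path cells x genes matrix (same formats as [load_slice]).
#' @param labels_path CSV with columns `spot_id,cell_type` (one row per cell,
#'   matched by order or by matrix row names).
#' @param fmt matrix format.
#' @inheritParams load_slice
#' @return An [sc_reference].
#' @export
load_reference <- function(matrix_path, labels_path, fmt = c("csv", "tsv", "mtx"),
                           rownames_path = NULL, colnames_path = NULL) {
  fmt <- match.arg(fmt)
  if (fmt == "mtx") {
    m <- as.matrix(Matrix::readMM(matrix_path))
    if (is.null(rownames_path)) rownames_path <- paste0(matrix_path, ".rownames")
    if (is.null(colnames_path)) colnames_path <- paste0(matrix_path, ".colnames")
    if (file.exists(rownames_path)) rownames(m) <- readLines(rownames_path)
    if (file.exists(colnames_path)) colnames(m) <- readLines(colnames_path)
  } else {
    sep <- if (fmt == "csv") "," else "\t"
    m <- as.matrix(utils::read.table(matrix_path, sep = sep, header = TRUE,
                                     row.names = 1, check.names = FALSE))
  }
  lab <- utils::read.csv(labels_path, check.names = FALSE)
  if (nrow(lab) != nrow(m)) stop("label table must have one row per cell")
  if (!is.null(rownames(m)) && "spot_id" %in% names(lab) &&
      all(lab$spot_id %in% rownames(m))) {
    m <- m[match(lab$spot_id, rownames(m)), , drop = FALSE]
  }
  sc_reference(m, lab$cell_type)
}

#' Restrict a reference and slices to their common gene space
#'
#' Both the deconvolution model and its pseudo-spot training set must live in
#' one gene space, so every object is restricted to the gene intersection in
#' a single fixed order (the reference order). Idempotent.
#'
#' @param ref an [sc_reference].
#' @param slices a list of [slice_data] objects (a bare `slice_data` is
#'   accepted and wrapped).
#' @return A list with elements `ref` and `slices` in the shared gene space.
#' @export
harmonize_genes <- function(ref, slices) {
  if (inherits(slices, "slice_data")) slices <- list(slices)
  common <- colnames(ref$counts)
  for (s in slices) common <- intersect(common, colnames(s$counts))
  if (length(common) == 0) stop("empty gene intersection")
  ref$counts <- ref$counts[, common, drop = FALSE]
  slices <- lapply(slices, function(s) {
    s$counts <- s$counts[, common, drop = FALSE]
    s
  })
  list(ref = ref, slices = slices)
}

#' Library-size normalization with log transform
#'
#' Scales each row (spot/cell) to the median total count of the matrix and
#' applies log1p. Model inputs use this normalization by default; raw counts
#' are kept for count-level operations such as downsampling.
#'
#' @param counts spots/cells x genes matrix.
#' @param method `"lognorm"` or `"raw"` (identity).
#' @param scale_to target row total; default the median observed total.
#' @return A matrix of the same shape.
#' @export
normalize_counts <- function(counts, method = c("lognorm", "raw"),
                             scale_to = NULL) {
  method <- match.arg(method)
  if (method == "raw") return(counts)
  tot <- rowSums(counts)
  tot[tot == 0] <- 1
  if (is.null(scale_to)) scale_to <- stats::median(tot)
  log1p(counts / tot * scale_to)
}

# Derived per-module seeds: one user-facing seed, fixed offsets per stage so
# stages stay reproducible independently of one another. Kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483587)
}
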