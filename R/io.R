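#' Annotated counts container
#'
#' Lightweight container for an observations-by-genes count matrix (cells or
#' spots in rows) with unique row and gene identifiers, optional per-row
#' cell-type labels, and a normalization flag.
#'
#' @param mat numeric matrix, rows = observations, columns = genes; must be
#'   nonnegative and carry unique dimnames (or supply `row_ids`/`gene_ids`).
#' @param labels optional character/factor vector of per-row labels (cell
#'   types), length `nrow(mat)`.
#' @param normalized one of `"raw"` or `"CPM"`.
#' @param row_ids,gene_ids optional identifier vectors overriding dimnames.
#' @return an object of class `annotated_counts`: a list with elements
#'   `matrix`, `labels`, `normalized`.
#' @export
annotated_counts <- function(mat, labels = NULL, normalized = c("raw", "CPM"),
                             row_ids = NULL, gene_ids = NULL) {
  normalized <- match.arg(normalized)
  mat <- as.matrix(mat)
  if (!is.null(row_ids)) rownames(mat) <- row_ids
  if (!is.null(gene_ids)) colnames(mat) <- gene_ids
  if (is.null(rownames(mat)))
    rownames(mat) <- sprintf("obs%d", seq_len(nrow(mat)))
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("gene%d", seq_len(ncol(mat)))
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(mat))
      stop("labels length (", length(labels), ") does not match rows (",
           nrow(mat), ")")
  }
  obj <- structure(list(matrix = mat, labels = labels,
                        normalized = normalized),
                   class = "annotated_counts")
  validate_annotated_counts(obj)
  obj
}

#' @export
print.annotated_counts <- function(x, ...) {
  cat(sprintf("annotated_counts: %d x %d (%s)%s\n",
              nrow(x$matrix), ncol(x$matrix), x$normalized,
              if (is.null(x$labels)) "" else
                sprintf(", %d label classes", length(unique(x$labels)))))
  invisible(x)
}

#' Validate an annotated_counts object
#'
#' Checks nonnegativity, identifier uniqueness and, for CPM matrices, that
#' every nonzero row sums to 1e6 within relative tolerance 1e-6.
#' @param x annotated_counts.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_annotated_counts <- function(x) {
  m <- x$matrix
  if (anyNA(m) || any(!is.finite(m))) stop("counts contain NA/non-finite values")
  if (any(m < 0)) stop("counts contain negative entries")
  if (anyDuplicated(rownames(m))) stop("duplicate row ids")
  if (anyDuplicated(colnames(m))) stop("duplicate gene ids")
  if (identical(x$normalized, "CPM")) {
    rs <- rowSums(m)
    nz <- rs > 0
    if (any(abs(rs[nz] - 1e6) > 1e-6 * 1e6))
      stop("CPM-flagged matrix has nonzero rows not summing to 1e6")
  }
  invisible(x)
}

#' Read a counts matrix from Matrix Market + id lists
#'
#' @param mtx_path Matrix Market file (observations x genes).
#' @param row_ids_path text file, one observation id per line.
#' @param gene_ids_path text file, one gene id per line.
#' @param labels_path optional CSV with columns `row_id,label`.
#' @return annotated_counts (raw).
#' @export
read_counts <- function(mtx_path, row_ids_path, gene_ids_path,
                        labels_path = NULL) {
  for (f in c(mtx_path, row_ids_path, gene_ids_path, labels_path))
    if (!is.null(f) && !file.exists(f)) stop("file not found: ", f)
  m <- as.matrix(Matrix::readMM(mtx_path))
  row_ids <- readLines(row_ids_path)
  gene_ids <- readLines(gene_ids_path)
  row_ids <- row_ids[nzchar(row_ids)]
  gene_ids <- gene_ids[nzchar(gene_ids)]
  if (length(row_ids) != nrow(m))
    stop("row id count in ", row_ids_path, " (", length(row_ids),
         ") does not match matrix rows (", nrow(m), ")")
  if (length(gene_ids) != ncol(m))
    stop("gene id count in ", gene_ids_path, " (", length(gene_ids),
         ") does not match matrix columns (", ncol(m), ")")
  labels <- NULL
  if (!is.null(labels_path)) {
    lab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
    if (ncol(lab) < 2) stop("labels CSV needs two columns (row_id,label)")
    idx <- match(row_ids, lab[[1]])
    if (anyNA(idx)) stop("labels CSV missing ids present in ", row_ids_path)
    labels <- lab[[2]][idx]
  }
  annotated_counts(m, labels = labels, row_ids = row_ids,
                   gene_ids = gene_ids)
}

#' Write an annotated_counts object to Matrix Market + id lists
#'
#' @param x annotated_counts.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix, default "counts".
#' @return invisibly, the paths written.
#' @export
write_counts <- function(x, dir, prefix = "counts") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c(".mtx", "_rows.txt", "_genes.txt",
                                           "_labels.csv")))
  Matrix::writeMM(methods::as(Matrix::Matrix(x$matrix, sparse = TRUE),
                              "generalMatrix"), paths[1])
  writeLines(rownames(x$matrix), paths[2])
  writeLines(colnames(x$matrix), paths[3])
  if (!is.null(x$labels)) {
    utils::write.csv(data.frame(row_id = rownames(x$matrix),
                                label = x$labels),
                     paths[4], row.names = FALSE)
  } else paths <- paths[1:3]
  invisible(paths)
}

#' Spot geometry container
#'
#' @param spot_ids character vector of barcodes.
#' @param centers numeric matrix/data.frame with columns x, y in
#'   full-resolution pixels (x = image column, y = image row).
#' @param spot_diameter_px spot diameter in pixels (> 0).
#' @param microns_per_px physical pixel size.
#' @param in_tissue logical vector per spot.
#' @return object of class `spot_geometry`.
#' @export
spot_geometry <- function(spot_ids, centers, spot_diameter_px,
                          microns_per_px = 1,
                          in_tissue = rep(TRUE, length(spot_ids))) {
  centers <- as.matrix(centers)
  colnames(centers) <- c("x", "y")
  if (nrow(centers) != length(spot_ids)) stop("centers/spot_ids mismatch")
  if (anyDuplicated(spot_ids)) stop("duplicate spot ids")
  if (any(!is.finite(centers))) stop("non-finite spot centers")
  if (!is.numeric(spot_diameter_px) || spot_diameter_px <= 0)
    stop("spot_diameter_px must be positive")
  if (microns_per_px <= 0) stop("microns_per_px must be positive")
  rownames(centers) <- spot_ids
  structure(list(spot_ids = spot_ids, centers = centers,
                 spot_diameter_px = spot_diameter_px,
                 microns_per_px = microns_per_px,
                 in_tissue = as.logical(in_tissue)),
            class = "spot_geometry")
}

#' Read Visium-style spot geometry
#'
#' Accepts tissue_positions CSV (with or without header; columns barcode,
#' in_tissue, array_row, array_col, pxl_row_in_fullres, pxl_col_in_fullres)
#' plus a scalefactors JSON holding `spot_diameter_fullres` and a
#' microns-per-pixel entry (`microns_per_pixel` or `microns_per_px`).
#'
#' @param positions_csv path to positions CSV.
#' @param scalefactors_json path to scalefactors JSON.
#' @return spot_geometry; centers are (pxl_col, pxl_row).
#' @export
read_spot_geometry <- function(positions_csv, scalefactors_json) {
  if (!file.exists(positions_csv)) stop("file not found: ", positions_csv)
  if (!file.exists(scalefactors_json)) stop("file not found: ", scalefactors_json)
  first <- readLines(positions_csv, n = 1)
  has_header <- grepl("barcode", first, fixed = TRUE)
  pos <- utils::read.csv(positions_csv, header = has_header,
                         stringsAsFactors = FALSE)
  cols <- c("barcode", "in_tissue", "array_row", "array_col",
            "pxl_row_in_fullres", "pxl_col_in_fullres")
  if (has_header) {
    if (!all(cols %in% names(pos)))
      stop("positions CSV missing columns: ",
           paste(setdiff(cols, names(pos)), collapse = ", "))
    pos <- pos[cols]
  } else {
    if (ncol(pos) < 6) stop("positions CSV must have 6 columns")
    names(pos)[1:6] <- cols
  }
  sf <- tryCatch(jsonlite::read_json(scalefactors_json),
                 error = function(e) stop("malformed scalefactors JSON: ",
                                          conditionMessage(e)))
  if (is.null(sf$spot_diameter_fullres))
    stop("scalefactors JSON missing spot_diameter_fullres")
  mpp <- sf$microns_per_pixel
  if (is.null(mpp)) mpp <- sf$microns_per_px
  if (is.null(mpp)) stop("scalefactors JSON missing microns-per-pixel entry")
  spot_geometry(spot_ids = as.character(pos$barcode),
                centers = cbind(x = pos$pxl_col_in_fullres,
                                y = pos$pxl_row_in_fullres),
                spot_diameter_px = as.numeric(sf$spot_diameter_fullres),
                microns_per_px = as.numeric(mpp),
                in_tissue = pos$in_tissue == 1)
}

#' Nucleus set container
#'
#' @param nucleus_ids character ids.
#' @param coords matrix/data.frame of (x, y) in full-resolution pixels.
#' @param assigned_spot optional spot id per nucleus (NA = out-spot).
#' @param assigned_type optional cell-type label per nucleus.
#' @return data.frame of class `nucleus_set` with columns nucleus_id, x, y,
#'   assigned_spot, assigned_type.
#' @export
nucleus_set <- function(nucleus_ids, coords, assigned_spot = NA_character_,
                        assigned_type = NA_character_) {
  coords <- as.matrix(coords)
  if (length(nucleus_ids) != nrow(coords)) stop("ids/coords mismatch")
  if (length(nucleus_ids) > 0 && any(!is.finite(coords)))
    stop("non-finite nucleus coordinates")
  df <- data.frame(nucleus_id = as.character(nucleus_ids),
                   x = as.numeric(coords[, 1]), y = as.numeric(coords[, 2]),
                   assigned_spot = rep_len(as.character(assigned_spot),
                                           length(nucleus_ids)),
                   assigned_type = rep_len(as.character(assigned_type),
                                           length(nucleus_ids)),
                   stringsAsFactors = FALSE)
  class(df) <- c("nucleus_set", "data.frame")
  df
}

#' Read a nuclei CSV (nucleus_id,x,y[,assigned_spot,assigned_type])
#' @param path CSV path.
#' @return nucleus_set.
#' @export
read_nuclei <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("nucleus_id", "x", "y")
  if (!all(need %in% names(df)))
    stop("nuclei CSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  nucleus_set(df$nucleus_id, cbind(df$x, df$y),
              assigned_spot = if ("assigned_spot" %in% names(df))
                df$assigned_spot else NA_character_,
              assigned_type = if ("assigned_type" %in% names(df))
                df$assigned_type else NA_character_)
}

#' Write a nucleus_set to CSV
#' @param nuclei nucleus_set.
#' @param path output CSV.
#' @return path, invisibly.
#' @export
write_nuclei <- function(nuclei, path) {
  utils::write.csv(as.data.frame(nuclei), path, row.names = FALSE)
  invisible(path)
}

#' Counts-per-million normalization
#'
#' Scales every row to sum to 1e6. All-zero rows are left at zero and
#' reported via a warning. Refuses already-normalized input.
#'
#' @param counts raw annotated_counts.
#' @return annotated_counts with `normalized = "CPM"`.
#' @export
cpm_normalize <- function(counts) {
  stopifnot(inherits(counts, "annotated_counts"))
  if (identical(counts$normalized, "CPM"))
    stop("input is already CPM-normalized; double normalization forbidden")
  m <- counts$matrix
  rs <- rowSums(m)
  zero <- rs == 0
  if (any(zero))
    warning(sum(zero), " all-zero row(s) left unscaled by CPM normalization")
  scl <- ifelse(zero, 0, 1e6 / rs)
  out <- m * scl
  annotated_counts(out, labels = counts$labels, normalized = "CPM")
}

#' Restrict two count matrices to their shared gene universe
#'
#' Case-sensitive exact intersection of gene ids, preserving the gene order
#' of `x`; the number of genes dropped on each side is reported.
#'
#' @param x,y annotated_counts.
#' @return list(x =, y =) restricted to common genes.
#' @export
intersect_genes <- function(x, y) {
  common <- intersect(colnames(x$matrix), colnames(y$matrix))
  if (length(common) == 0) stop("no shared genes between the two matrices")
  dx <- ncol(x$matrix) - length(common)
  dy <- ncol(y$matrix) - length(common)
  if (dx + dy > 0)
    message("intersect_genes: dropped ", dx, " genes from x and ", dy,
            " from y; ", length(common), " shared genes kept")
  sub <- function(a) annotated_counts(a$matrix[, common, drop = FALSE],
                                      labels = a$labels,
                                      normalized = a$normalized)
  list(x = sub(x), y = sub(y))
}

#' Pipeline configuration with validated defaults
#'
#' Bundles the tunable parameters of the whole pipeline. Marker selection:
#' `l_fold` (fold-change threshold), `l_lambda` (max p-value), `l_cover`
#' (coverage threshold), `v` (fold-change quantile), `n_select` (markers per
#' type). Decomposition: `l_p` (image-free presence threshold). Inference:
#' `n_iterations`, `learning_rate`, `seed`. Imputation: `gp_length_scale`
#' (um; NULL = 2x spot pitch), `gp_noise`, `k_neighbors`. Simulation:
#' `noise_level`.
#'
#' @param l_fold,l_lambda,l_cover,v,n_select marker-selection parameters.
#' @param l_p presence threshold in `[0, 1)`.
#' @param n_iterations,learning_rate,seed optimizer settings.
#' @param gp_length_scale,gp_noise,k_neighbors imputation settings.
#' @param noise_level one of none/small/medium/large.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(l_fold = 1.5, l_lambda = 0.1, l_cover = 0.60,
                            v = 0.15, n_select = 50, l_p = 0.05,
                            n_iterations = 8000, learning_rate = 0.01,
                            seed = 1L, gp_length_scale = NULL,
                            gp_noise = 1e-4, k_neighbors = 10,
                            noise_level = c("none", "small", "medium",
                                            "large")) {
  noise_level <- match.arg(noise_level)
  stopifnot(l_fold > 0, l_lambda > 0, l_lambda <= 1,
            l_cover >= 0, l_cover <= 1, v > 0, v < 1,
            n_select >= 1, l_p >= 0, l_p < 1,
            n_iterations >= 1, learning_rate > 0,
            gp_noise >= 0, k_neighbors >= 1)
  structure(list(l_fold = l_fold, l_lambda = l_lambda, l_cover = l_cover,
                 v = v, n_select = as.integer(n_select), l_p = l_p,
                 n_iterations = as.integer(n_iterations),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 gp_length_scale = gp_length_scale, gp_noise = gp_noise,
                 k_neighbors = as.integer(k_neighbors),
                 noise_level = noise_level),
            class = "pipeline_config")
}
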