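# Marker selection and signature-matrix construction from annotated scRNA-seq.

# Per-type mean expression (T x G) of a labelled matrix.
type_means <- function(m, labels) {
  types <- sort(unique(labels))
  z <- rowsum(m, group = labels)       # sums per type, rows in sort order
  n <- as.vector(table(labels)[rownames(z)])
  z / n
}

# Quantile type 7 tolerating +Inf entries (interpolation toward Inf is Inf).
quantile7_inf <- function(x, v) {
  x <- unname(sort(x))
  n <- length(x)
  if (n == 1) return(x)
  h <- (n - 1) * v
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  frac <- h - (lo - 1)
  if (frac == 0) return(x[lo])
  if (is.infinite(x[hi])) return(x[hi])
  x[lo] + frac * (x[hi] - x[lo])
}

# Pairwise fold ratios with the degenerate-mean conventions:
# 0/0 -> 1 (uninformative), x/0 -> +Inf for x > 0.
fold_ratios <- function(z_t, z_other) {
  r <- ifelse(z_other == 0, ifelse(z_t == 0, 1, Inf), z_t / z_other)
  r
}

#' Fold-change quantile of a gene for one cell type
#'
#' The v-th sample quantile (linear interpolation, type 7) of the fold
#' changes of the type-t mean CPM of gene g against every other type's mean.
#' A ratio of two zero means is treated as 1; positive over zero is +Inf.
#'
#' @param Y_cpm CPM-normalized annotated_counts with labels, or a matrix
#'   (then supply `labels`).
#' @param labels per-cell type labels (ignored when `Y_cpm` carries them).
#' @param gene gene id or column index.
#' @param type cell type whose markers are sought.
#' @param v quantile level in (0, 1).
#' @return scalar fold-change quantile.
#' @export
fold_change_quantile <- function(Y_cpm, labels = NULL, gene, type, v) {
  m <- if (inherits(Y_cpm, "annotated_counts")) Y_cpm$matrix else Y_cpm
  if (inherits(Y_cpm, "annotated_counts") && is.null(labels))
    labels <- Y_cpm$labels
  if (!type %in% labels) stop("type '", type, "' absent from labels")
  z <- type_means(m[, gene, drop = FALSE], labels)
  zt <- z[type, 1]
  zo <- z[setdiff(rownames(z), type), 1]
  quantile7_inf(fold_ratios(zt, zo), v)
}

#' One-sided Welch z-test that a gene's mean is higher in type t than t'
#'
#' Tests H0: z_t <= z_t' against H1: z_t > z_t' on per-cell CPM values.
#' With both sample variances zero: p = 0.5 when means are equal, 0 when the
#' type-t mean is larger, 1 otherwise.
#'
#' @inheritParams fold_change_quantile
#' @param type2 the comparison type t'.
#' @return one-sided p-value.
#' @export
marker_z_test <- function(Y_cpm, labels = NULL, gene, type, type2) {
  m <- if (inherits(Y_cpm, "annotated_counts")) Y_cpm$matrix else Y_cpm
  if (inherits(Y_cpm, "annotated_counts") && is.null(labels))
    labels <- Y_cpm$labels
  a <- m[labels == type, gene]
  b <- m[labels == type2, gene]
  if (length(a) < 2 || length(b) < 2)
    stop("z-test needs at least 2 cells per group")
  va <- stats::var(a); vb <- stats::var(b)
  d <- mean(a) - mean(b)
  se <- sqrt(va / length(a) + vb / length(b))
  if (se == 0) return(if (d == 0) 0.5 else if (d > 0) 0 else 1)
  stats::pnorm(d / se, lower.tail = FALSE)
}

#' Coverage of a gene within a cell type
#'
#' Fraction of type-t cells with nonzero expression of the gene.
#' @inheritParams fold_change_quantile
#' @param Y annotated_counts or matrix (raw or CPM; zero pattern identical).
#' @return fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(Y, labels = NULL, gene, type) {
  m <- if (inherits(Y, "annotated_counts")) Y$matrix else Y
  if (inherits(Y, "annotated_counts") && is.null(labels)) labels <- Y$labels
  if (!type %in% labels) stop("type '", type, "' absent from labels")
  mean(m[labels == type, gene] > 0)
}

#' Select per-type marker genes
#'
#' A gene is a type-t candidate when (1) the v-quantile of its fold changes
#' against all other types exceeds `l_fold`, (2) the largest one-sided
#' z-test p-value against any other type is below `l_lambda`, and (3) its
#' coverage in type-t cells exceeds `l_cover`. Candidates are ranked per
#' type by fold-change quantile (ties broken by gene id) and the top
#' `n_select` kept; the marker panel is the union over types.
#'
#' @param Y_cpm CPM-normalized annotated_counts with labels.
#' @param config pipeline_config (uses l_fold, l_lambda, l_cover, v,
#'   n_select).
#' @param labels optional override of the label vector.
#' @return list with `markers` (character union, in gene order of Y),
#'   `per_type` (named list of per-type ranked marker vectors) and `stats`
#'   (data.frame of gene, type, fold_quantile, max_pvalue, coverage,
#'   selected, rank).
#' @export
select_markers <- function(Y_cpm, config = pipeline_config(),
                           labels = NULL) {
  m <- Y_cpm$matrix
  if (is.null(labels)) labels <- Y_cpm$labels
  if (is.null(labels)) stop("cell-type labels required")
  types <- sort(unique(labels))
  if (length(types) < 2) stop("marker selection needs at least 2 types")
  genes <- colnames(m)
  G <- length(genes)

  z <- type_means(m, labels)                       # T x G mean CPM
  nt <- as.vector(table(labels)[types])
  vt <- rowsum(m^2, labels)[types, , drop = FALSE]
  # per-type sample variance per gene
  vt <- sweep(vt - sweep(z^2, 1, nt, "*"), 1, pmax(nt - 1, 1), "/")
  vt[vt < 0] <- 0                                  # numerical guard
  cover <- rowsum((m > 0) * 1, labels)[types, , drop = FALSE] / nt

  stats_list <- vector("list", length(types))
  per_type <- stats::setNames(vector("list", length(types)), types)
  for (ti in seq_along(types)) {
    t <- types[ti]
    others <- setdiff(seq_along(types), ti)
    fq <- numeric(G); maxp <- numeric(G)
    for (g in seq_len(G)) {
      fq[g] <- quantile7_inf(fold_ratios(z[ti, g], z[others, g]), config$v)
      se <- sqrt(vt[ti, g] / nt[ti] + vt[others, g] / nt[others])
      d <- z[ti, g] - z[others, g]
      p <- ifelse(se == 0, ifelse(d == 0, 0.5, ifelse(d > 0, 0, 1)),
                  stats::pnorm(d / se, lower.tail = FALSE))
      maxp[g] <- max(p)
    }
    cand <- fq > config$l_fold & maxp < config$l_lambda &
      cover[ti, ] > config$l_cover
    sel <- rep(FALSE, G); rank <- rep(NA_integer_, G)
    if (any(cand)) {
      idx <- which(cand)
      ord <- idx[order(-fq[idx], genes[idx])]
      keep <- ord[seq_len(min(config$n_select, length(ord)))]
      sel[keep] <- TRUE
      rank[keep] <- seq_along(keep)
      per_type[[t]] <- genes[keep]
    } else {
      warning("no marker candidates for type '", t, "'")
      per_type[[t]] <- character(0)
    }
    stats_list[[ti]] <- data.frame(gene = genes, type = t,
                                   fold_quantile = fq, max_pvalue = maxp,
                                   coverage = cover[ti, ], selected = sel,
                                   rank = rank, stringsAsFactors = FALSE)
  }
  stats <- do.call(rbind, stats_list)
  rownames(stats) <- NULL
  markers <- genes[genes %in% unique(unlist(per_type))]
  list(markers = markers, per_type = per_type, stats = stats)
}

#' Build a cell-type signature matrix by pooled maximum likelihood
#'
#' For every type, the signature row is the pooled count of each gene over
#' that type's cells divided by the pooled total over the gene subset, so
#' rows sum to 1. `nu` records the per-type mean library size over the same
#' genes (used to convert gene-contribution scores to cell-number
#' proportions).
#'
#' @param Y annotated_counts with labels (raw or CPM; the estimator is
#'   scale-invariant per cell only under equal library sizes, so CPM input
#'   is the conventional choice).
#' @param gene_subset character vector of genes to keep (default all).
#' @param labels optional override of labels.
#' @return object of class `signature_matrix`: list(phi = T x G matrix with
#'   unit row sums, type_ids, gene_ids, nu).
#' @export
build_signature <- function(Y, gene_subset = NULL, labels = NULL) {
  m <- Y$matrix
  if (is.null(labels)) labels <- Y$labels
  if (is.null(labels)) stop("cell-type labels required")
  if (!is.null(gene_subset)) {
    missing <- setdiff(gene_subset, colnames(m))
    if (length(missing) > 0)
      stop("gene subset not in matrix: ", paste(utils::head(missing, 5),
                                                collapse = ", "))
    m <- m[, gene_subset, drop = FALSE]
  }
  if (ncol(m) == 0) stop("empty gene subset")
  types <- sort(unique(labels))
  pooled <- rowsum(m, labels)[types, , drop = FALSE]
  tot <- rowSums(pooled)
  if (any(tot == 0))
    stop("type(s) with zero pooled counts over the gene subset: ",
         paste(types[tot == 0], collapse = ", "))
  phi <- pooled / tot
  lib <- rowSums(m)
  nu <- as.vector(tapply(lib, labels, mean)[types])
  structure(list(phi = phi, type_ids = types, gene_ids = colnames(m),
                 nu = nu), class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("signature_matrix: %d types x %d genes\n",
              length(x$type_ids), length(x$gene_ids)))
  invisible(x)
}

#' Write a signature matrix to CSV (types x genes; nu as final column)
#' @param sig signature_matrix.
#' @param path output CSV.
#' @return path, invisibly.
#' @export
write_signature <- function(sig, path) {
  df <- data.frame(type = sig$type_ids, sig$phi, nu = sig$nu,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a signature matrix written by [write_signature()]
#' @param path CSV path.
#' @return signature_matrix.
#' @export
read_signature <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- setdiff(names(df), c("type", "nu"))
  phi <- as.matrix(df[genes])
  rownames(phi) <- df$type
  structure(list(phi = phi, type_ids = df$type, gene_ids = genes,
                 nu = df$nu), class = "signature_matrix")
}
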