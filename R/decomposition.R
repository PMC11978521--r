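# From proportions to integer cell counts and per-cell expression (iscRNA).

#' Apportion an integer cell count across types
#'
#' Solves min sum_t |n_t/N - p_t| subject to sum n_t = N over nonnegative
#' integers by largest-remainder apportionment: floor(N p), then distribute
#' the remaining cells by descending fractional remainder (ties broken by
#' larger proportion, then type index). The result is an optimizer of the
#' L1 objective.
#'
#' @param p simplex vector over T types.
#' @param N nonnegative integer total cell count.
#' @return integer vector summing to `N`.
#' @export
apportion_cells <- function(p, N) {
  if (N < 0) stop("negative cell count")
  if (abs(sum(p) - 1) > 1e-6 || any(p < 0)) stop("p is not a simplex")
  tgt <- N * p
  n <- floor(tgt)
  rem <- tgt - n
  left <- N - sum(n)
  if (left > 0) {
    ord <- order(-rem, -p, seq_along(p))
    take <- ord[seq_len(left)]
    n[take] <- n[take] + 1
  }
  as.integer(n)
}

#' Threshold proportions when no image is available
#'
#' Types with proportion below `l_p` are zeroed as lacking evidence of
#' presence; survivors are renormalized to sum 1. If nothing survives the
#' single largest type is kept.
#'
#' @param p simplex vector.
#' @param l_p presence threshold in `[0, 1)`.
#' @return updated simplex vector.
#' @export
threshold_proportions <- function(p, l_p) {
  if (l_p < 0 || l_p >= 1) stop("l_p must be in [0, 1)")
  keep <- p >= l_p & p > 0
  if (!any(keep)) {
    message("no type above threshold; keeping the argmax type")
    keep <- seq_along(p) == which.max(p)
  }
  out <- ifelse(keep, p, 0)
  out / sum(out)
}

#' Decompose one spot's counts across cell types
#'
#' Allocation weights omega_gt = p_t phi_tg / sum_t' p_t' phi_t'g split each
#' gene's count among the present types; u_tg = x_g * omega_gt, so the type
#' rows sum back to the spot counts exactly. Genes with zero denominator
#' but nonzero counts are allocated proportionally to p (logged fallback).
#'
#' @param x length-G count vector for one spot.
#' @param p_tilde updated simplex over T types.
#' @param phi signature_matrix over all G genes.
#' @return list(U = T x G expression matrix, omega = T x G weights).
#' @export
decompose_spot <- function(x, p_tilde, phi) {
  pm <- if (inherits(phi, "signature_matrix")) phi$phi else phi
  if (length(x) != ncol(pm)) stop("gene dimension mismatch")
  if (length(p_tilde) != nrow(pm)) stop("type dimension mismatch")
  num <- pm * p_tilde                 # T x G, row t scaled by p_t
  den <- colSums(num)
  omega <- sweep(num, 2, ifelse(den > 0, den, 1), "/")
  bad <- den == 0
  if (any(bad & x > 0)) {
    message("decompose_spot: ", sum(bad & x > 0),
            " gene(s) with zero signature mass allocated by proportions")
  }
  if (any(bad)) {
    fallback <- if (sum(p_tilde) > 0) p_tilde / sum(p_tilde)
                else rep(1 / nrow(pm), nrow(pm))
    omega[, bad] <- fallback
  }
  U <- sweep(omega, 2, x, "*")
  # float-exact conservation: fold the rounding residual of each gene into
  # its dominant type so column sums equal x bit-for-bit
  top <- max.col(t(omega), ties.method = "first")
  for (k in 1:3) {
    resid <- x - colSums(U)
    if (all(resid == 0)) break
    U[cbind(top, seq_along(x))] <- U[cbind(top, seq_along(x))] + resid
  }
  dimnames(U) <- dimnames(pm)
  list(U = U, omega = omega)
}

#' Decompose every spot of a count matrix
#'
#' @param X annotated_counts or S x G matrix of raw spot counts.
#' @param P_tilde S x T matrix of updated proportions.
#' @param phi signature_matrix over the G genes.
#' @return list of `decompose_spot` results, one per spot, named by spot id.
#' @export
decompose_all <- function(X, P_tilde, phi) {
  m <- if (inherits(X, "annotated_counts")) X$matrix else X
  if (nrow(m) != nrow(P_tilde)) stop("spot dimension mismatch")
  out <- lapply(seq_len(nrow(m)), function(s)
    decompose_spot(m[s, ], P_tilde[s, ], phi))
  names(out) <- rownames(m)
  out
}

#' Split a spot's type-level expression among its cells
#'
#' Mode `"expected"` gives every type-t cell the mean profile u_t / n_t
#' (real-valued, posterior-mean flavor). Mode `"sampled"` splits the
#' rounded integer counts of u_t multinomially among the n_t cells with a
#' seeded generator. Both modes conserve the type totals.
#'
#' @param U T x G type-level expression of one spot.
#' @param n integer vector of cells per type (sum = N_s).
#' @param mode `"expected"` or `"sampled"`.
#' @param seed integer seed for sampled mode.
#' @return matrix with one row per cell, a `type` attribute giving each
#'   row's cell type.
#' @export
partition_to_cells <- function(U, n, mode = c("expected", "sampled"),
                               seed = 1L) {
  mode <- match.arg(mode)
  if (length(n) != nrow(U)) stop("type dimension mismatch")
  if (any(rowSums(U) > 1e-9 & n == 0))
    stop("nonzero expression for type(s) with zero cells")
  total <- sum(n)
  out <- matrix(0, total, ncol(U))
  colnames(out) <- colnames(U)
  types <- rep(rownames(U), n)
  if (total == 0) return(structure(out, type = character(0)))
  if (mode == "sampled") {
    set.seed(seed)
    # integerize each gene column by largest remainder so the column total
    # (the spot's gene count) is conserved across types exactly
    Cnt <- matrix(0L, nrow(U), ncol(U))
    for (g in seq_len(ncol(U))) {
      tot <- round(sum(U[, g]))
      if (tot == 0) next
      pr <- if (sum(U[, g]) > 0) U[, g] / sum(U[, g])
            else rep(1 / nrow(U), nrow(U))
      pr[n == 0] <- 0
      if (sum(pr) == 0) pr[n > 0] <- 1
      pr <- pr / sum(pr)
      Cnt[, g] <- apportion_cells(pr, tot)
    }
  }
  row0 <- 0
  for (t in seq_len(nrow(U))) {
    if (n[t] == 0) next
    idx <- row0 + seq_len(n[t])
    if (mode == "expected") {
      out[idx, ] <- matrix(rep(U[t, ] / n[t], each = n[t]), nrow = n[t])
    } else {
      for (g in which(Cnt[t, ] > 0)) {
        draws <- tabulate(sample.int(n[t], Cnt[t, g], replace = TRUE),
                          nbins = n[t])
        out[idx, g] <- draws
      }
    }
    row0 <- row0 + n[t]
  }
  structure(out, type = types)
}

#' Randomly label in-spot nuclei with cell types
#'
#' Within each spot, a seeded random permutation of its nuclei receives
#' labels such that exactly n_st nuclei carry type t.
#'
#' @param nuclei nucleus_set with `assigned_spot` filled.
#' @param n_st S x T integer matrix (rownames = spot ids, colnames =
#'   types).
#' @param seed integer seed.
#' @return nucleus_set with `assigned_type` filled for in-spot nuclei.
#' @export
annotate_in_spot_nuclei <- function(nuclei, n_st, seed = 1L) {
  set.seed(seed)
  types <- colnames(n_st)
  for (s in rownames(n_st)) {
    idx <- which(!is.na(nuclei$assigned_spot) & nuclei$assigned_spot == s)
    ns <- n_st[s, ]
    if (length(idx) != sum(ns))
      stop("spot ", s, ": ", length(idx), " nuclei but composition has ",
           sum(ns), " cells")
    if (length(idx) == 0) next
    labels <- rep(types, ns)
    nuclei$assigned_type[sample(idx)] <- labels
  }
  nuclei
}

#' Assemble per-cell expression profiles for in-spot nuclei (iscRNA)
#'
#' Runs [partition_to_cells()] for every spot and attaches the resulting
#' profiles to that spot's typed nuclei. Within a spot, cells of the same
#' type are interchangeable; profiles are assigned to nuclei of matching
#' type in nucleus order.
#'
#' @param decomposed list from [decompose_all()].
#' @param nuclei typed nucleus_set (see [annotate_in_spot_nuclei()]).
#' @param n_st S x T integer composition matrix.
#' @param mode,seed passed to [partition_to_cells()].
#' @return object of class `cell_profile_set`: list(expression = cells x
#'   genes matrix, meta = data.frame(nucleus_id, spot, type, x, y,
#'   provenance)).
#' @export
build_cell_profiles <- function(decomposed, nuclei, n_st,
                                mode = c("expected", "sampled"),
                                seed = 1L) {
  mode <- match.arg(mode)
  G <- ncol(decomposed[[1]]$U)
  rows <- list(); meta <- list()
  for (s in names(decomposed)) {
    ns <- n_st[s, ]
    if (sum(ns) == 0) next
    prof <- partition_to_cells(decomposed[[s]]$U, ns, mode = mode,
                               seed = seed + match(s, names(decomposed)))
    ptypes <- attr(prof, "type")
    idx <- which(!is.na(nuclei$assigned_spot) & nuclei$assigned_spot == s)
    ord <- idx[order(match(nuclei$assigned_type[idx], colnames(n_st)))]
    # prof rows are grouped by type in colnames(n_st) order
    rows[[s]] <- prof
    meta[[s]] <- data.frame(nucleus_id = nuclei$nucleus_id[ord],
                            spot = s, type = ptypes,
                            x = nuclei$x[ord], y = nuclei$y[ord],
                            provenance = "decomposed",
                            stringsAsFactors = FALSE)
  }
  expression <- do.call(rbind, rows)
  meta <- do.call(rbind, meta)
  rownames(expression) <- meta$nucleus_id
  rownames(meta) <- NULL
  structure(list(expression = expression, meta = meta),
            class = "cell_profile_set")
}

#' @export
print.cell_profile_set <- function(x, ...) {
  cat(sprintf("cell_profile_set: %d cells x %d genes (%s)\n",
              nrow(x$expression), ncol(x$expression),
              paste(names(table(x$meta$provenance)), collapse = "/")))
  invisible(x)
}

#' Write a cell_profile_set as Matrix Market + metadata CSV
#' @param cells cell_profile_set.
#' @param dir output directory.
#' @return invisibly, paths written.
#' @export
write_cell_profiles <- function(cells, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "iscrna.mtx")
  Matrix::writeMM(methods::as(Matrix::Matrix(cells$expression,
                                             sparse = TRUE),
                              "generalMatrix"), p1)
  writeLines(rownames(cells$expression), file.path(dir, "iscrna_cells.txt"))
  writeLines(colnames(cells$expression), file.path(dir, "iscrna_genes.txt"))
  utils::write.csv(cells$meta, file.path(dir, "iscrna_meta.csv"),
                   row.names = FALSE)
  invisible(dir)
}
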