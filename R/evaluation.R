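# Per-spot proportion metrics and decomposition re-merge checks.

kl_base2 <- function(p, q) {
  nz <- p > 0
  sum(p[nz] * (log2(p[nz]) - log2(q[nz])))
}

#' Six evaluation metrics for one spot's proportion estimate
#'
#' Given an estimated and a true simplex over the same T cell types,
#' returns: absolute error sum|p - p*| (range 0-2); square error
#' sum (p - p*)^2; JSD, the square root of the mean base-2 KL divergence to
#' the midpoint (range 0-1); Pearson correlation with the constant
#' centering a = 1/T (equal to each vector's mean since both sum to 1);
#' cosine similarity; and the fraction of cells correctly mapped,
#' sum min(p, p*).
#'
#' @param p_est,p_true simplex vectors (sum to 1 within 1e-6).
#' @return named numeric vector `absolute_error`, `square_error`, `jsd`,
#'   `pearson`, `cosine`, `fraction_correct`. Pearson is NA when either
#'   vector has zero variance (logged).
#' @export
proportion_metrics <- function(p_est, p_true) {
  if (length(p_est) != length(p_true)) stop("length mismatch")
  for (v in list(p_est, p_true))
    if (any(v < 0) || abs(sum(v) - 1) > 1e-6)
      stop("inputs must be simplexes summing to 1")
  Tn <- length(p_est)
  m <- (p_est + p_true) / 2
  jsd <- sqrt(pmax(0, (kl_base2(p_est, m) + kl_base2(p_true, m)) / 2))
  a <- 1 / Tn
  de <- p_est - a; dt <- p_true - a
  denom <- sqrt(sum(de^2) * sum(dt^2))
  pearson <- if (denom == 0) {
    message("zero-variance proportion vector; Pearson undefined")
    NA_real_
  } else sum(de * dt) / denom
  cden <- sqrt(sum(p_est^2) * sum(p_true^2))
  cosine <- if (cden == 0) NA_real_ else sum(p_est * p_true) / cden
  c(absolute_error = sum(abs(p_est - p_true)),
    square_error = sum((p_est - p_true)^2),
    jsd = min(1, jsd),
    pearson = pearson,
    cosine = cosine,
    fraction_correct = sum(pmin(p_est, p_true)))
}

#' Merge per-cell profiles back into pseudo-spot counts
#'
#' Sums decomposed cell profiles by spot of origin; imputed (out-spot)
#' cells are excluded. In expected mode the result equals the decomposed
#' input matrix exactly by conservation.
#'
#' @param cells cell_profile_set.
#' @param spot_ids optional spot ordering for the output rows (default:
#'   spots in first-appearance order).
#' @return annotated_counts (raw) of pseudo-spot sums.
#' @export
merge_iscrna_to_pseudo_spots <- function(cells, spot_ids = NULL) {
  keep <- cells$meta$provenance == "decomposed" &
    !is.na(cells$meta$spot)
  expr <- cells$expression[keep, , drop = FALSE]
  spots <- cells$meta$spot[keep]
  pooled <- rowsum(expr, spots)
  if (!is.null(spot_ids)) {
    missing <- setdiff(spot_ids, rownames(pooled))
    if (length(missing) > 0) {
      pad <- matrix(0, length(missing), ncol(pooled),
                    dimnames = list(missing, colnames(pooled)))
      pooled <- rbind(pooled, pad)
    }
    pooled <- pooled[spot_ids, , drop = FALSE]
  } else {
    pooled <- pooled[unique(spots), , drop = FALSE]
  }
  annotated_counts(pooled)
}

#' Per-spot benchmarking report of estimated vs true proportions
#'
#' @param estimates S x T matrix of estimated proportions.
#' @param truth S x T matrix of true proportions (same spot/type order;
#'   matched by dimnames when present).
#' @param out_csv optional path; per-spot table plus summary rows written
#'   as CSV.
#' @param weights optional per-spot weights (e.g. N_s) for weighted
#'   summaries; default unweighted.
#' @return list of class `metric_report`: `per_spot` data.frame, `summary`
#'   (mean/median per metric), `overall_pearson` across the flattened
#'   matrices.
#' @export
benchmark_report <- function(estimates, truth, out_csv = NULL,
                             weights = NULL) {
  if (!all(dim(estimates) == dim(truth))) stop("dimension mismatch")
  if (!is.null(rownames(estimates)) && !is.null(rownames(truth))) {
    if (!setequal(rownames(estimates), rownames(truth)))
      stop("spot index mismatch between estimates and truth")
    truth <- truth[rownames(estimates), , drop = FALSE]
  }
  if (!is.null(colnames(estimates)) && !is.null(colnames(truth))) {
    if (!setequal(colnames(estimates), colnames(truth)))
      stop("type index mismatch between estimates and truth")
    truth <- truth[, colnames(estimates), drop = FALSE]
  }
  S <- nrow(estimates)
  per_spot <- t(vapply(seq_len(S), function(s)
    proportion_metrics(estimates[s, ], truth[s, ]), numeric(6)))
  per_spot <- data.frame(spot = rownames(estimates) %||%
                           sprintf("spot%d", seq_len(S)),
                         per_spot, stringsAsFactors = FALSE)
  w <- weights %||% rep(1, S)
  metric_cols <- setdiff(names(per_spot), "spot")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(k)
      stats::weighted.mean(per_spot[[k]], w, na.rm = TRUE), numeric(1)),
    median = vapply(metric_cols, function(k)
      stats::median(per_spot[[k]], na.rm = TRUE), numeric(1)))
  overall <- stats::cor(as.vector(estimates), as.vector(truth))
  rep <- structure(list(per_spot = per_spot, summary = summary,
                        overall_pearson = overall),
                   class = "metric_report")
  if (!is.null(out_csv)) {
    tab <- per_spot
    sm <- data.frame(spot = paste0("summary_mean_", summary$metric),
                     matrix(NA, nrow(summary), length(metric_cols),
                            dimnames = list(NULL, metric_cols)))
    for (i in seq_len(nrow(summary)))
      sm[i, summary$metric[i]] <- summary$mean[i]
    utils::write.csv(rbind(tab, sm), out_csv, row.names = FALSE)
  }
  rep
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report over %d spots (overall Pearson %.4f)\n",
              nrow(x$per_spot), x$overall_pearson))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
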