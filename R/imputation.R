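# Gaussian-process imputation of cell-type proportions at arbitrary slide
# coordinates, categorical typing of out-spot nuclei, and kernel smoothing
# of per-cell expression profiles for nuclei outside the capture areas.

sq_dist <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
}

# Median nearest-neighbor center distance; the natural pitch of the grid.
spot_pitch <- function(centers) {
  if (nrow(centers) < 2) return(1)
  d2 <- sq_dist(centers, centers)
  diag(d2) <- Inf
  stats::median(sqrt(apply(d2, 1, min)))
}

#' Fit a Gaussian-process proportion field over the slide
#'
#' One GP per cell type with an isotropic squared-exponential kernel over
#' spot-center coordinates, trained on the per-spot proportions. The prior
#' mean of each type's GP is its training mean, so far-field predictions
#' fall back to the slide-average composition. Hyperparameters are shared
#' across types; the length scale defaults to twice the spot pitch
#' (converted from um via the geometry's pixel size when configured in um).
#'
#' @param geometry spot_geometry (zero-radius point geometries, e.g. one
#'   nucleus per "spot", are supported unchanged).
#' @param P S x T matrix of per-spot proportions (rownames = spot ids).
#' @param config pipeline_config; `gp_length_scale` (um; NULL = 2x pitch)
#'   and `gp_noise` (variance) are used.
#' @param signal_var kernel signal variance; default 1.
#' @return object of class `proportion_field`.
#' @export
fit_proportion_field <- function(geometry, P, config = pipeline_config(),
                                 signal_var = 1) {
  ctr <- geometry$centers[rownames(P) %||% geometry$spot_ids, ,
                          drop = FALSE]
  if (nrow(ctr) < 10) stop("need at least 10 spots to fit the field")
  if (all(sq_dist(ctr, ctr) < 1e-12)) stop("degenerate geometry")
  ls_px <- if (is.null(config$gp_length_scale))
    2 * spot_pitch(ctr)
  else config$gp_length_scale / geometry$microns_per_px
  K <- signal_var * exp(-sq_dist(ctr, ctr) / (2 * ls_px^2))
  diag(K) <- diag(K) + config$gp_noise + 1e-10
  mu <- colMeans(P)
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), sweep(P, 2, mu)))
  structure(list(centers = ctr, alpha = alpha, mu = mu,
                 length_scale_px = ls_px, signal_var = signal_var,
                 noise_var = config$gp_noise,
                 type_ids = colnames(P),
                 slide_average = mu / sum(mu)),
            class = "proportion_field")
}

#' Predict cell-type proportions at arbitrary coordinates
#'
#' GP posterior means per type, clipped to `[0, 1]` and renormalized to a
#' simplex at every query point; degenerate all-zero predictions fall back
#' to the slide-average composition.
#'
#' @param field proportion_field.
#' @param coords n x 2 matrix of (x, y) pixel coordinates.
#' @return n x T matrix of simplex rows.
#' @export
predict_proportions <- function(field, coords) {
  coords <- matrix(as.numeric(coords), ncol = 2)
  if (any(!is.finite(coords))) stop("non-finite query coordinates")
  Ks <- field$signal_var *
    exp(-sq_dist(coords, field$centers) / (2 * field$length_scale_px^2))
  pred <- sweep(Ks %*% field$alpha, 2, field$mu, "+")
  pred <- pmin(pmax(pred, 0), 1)
  rs <- rowSums(pred)
  bad <- rs == 0
  if (any(bad)) {
    message(sum(bad), " degenerate prediction(s) fell back to the slide ",
            "average")
    pred[bad, ] <- matrix(rep(field$slide_average, sum(bad)),
                          nrow = sum(bad), byrow = TRUE)
    rs[bad] <- 1
  }
  out <- pred / rs
  colnames(out) <- field$type_ids
  out
}

#' Assign cell types to out-spot nuclei by sampling the proportion field
#'
#' Each out-spot nucleus draws its type from the categorical distribution
#' predicted at its coordinates (seeded).
#'
#' @param nuclei nucleus_set (only rows with `assigned_spot` NA are typed).
#' @param field proportion_field.
#' @param seed integer seed.
#' @return nucleus_set with `assigned_type` filled for out-spot nuclei.
#' @export
annotate_out_spot_nuclei <- function(nuclei, field, seed = 1L) {
  idx <- which(is.na(nuclei$assigned_spot))
  if (length(idx) == 0) return(nuclei)
  p <- predict_proportions(field, cbind(nuclei$x[idx], nuclei$y[idx]))
  set.seed(seed)
  draws <- vapply(seq_along(idx), function(i)
    sample(field$type_ids, 1, prob = p[i, ]), character(1))
  nuclei$assigned_type[idx] <- draws
  nuclei
}

#' Impute an expression profile for an out-spot nucleus
#'
#' Gaussian-kernel-weighted average of the expected per-cell type-t
#' profiles (u_t / n_t) from the k nearest spots containing type t.
#' Smoothing operates on per-cell profiles, not raw spot totals, so
#' cell-size effects do not leak. If no spot contains the type anywhere on
#' the slide an error is raised; bandwidth defaults to the GP length scale.
#'
#' @param coord length-2 (x, y) of the nucleus.
#' @param type cell-type label to impute.
#' @param decomposed list from [decompose_all()].
#' @param n_st S x T integer composition matrix (rownames = spot ids).
#' @param geometry spot_geometry.
#' @param bandwidth_px kernel bandwidth in pixels.
#' @param k number of nearest type-containing spots to average (default
#'   10).
#' @return length-G expression vector.
#' @export
impute_cell_expression <- function(coord, type, decomposed, n_st, geometry,
                                   bandwidth_px, k = 10) {
  if (!type %in% colnames(n_st)) stop("unknown type: ", type)
  has <- rownames(n_st)[n_st[, type] > 0]
  has <- intersect(has, names(decomposed))
  if (length(has) == 0)
    stop("type '", type, "' absent from every decomposed spot")
  ctr <- geometry$centers[has, , drop = FALSE]
  d2 <- (ctr[, "x"] - coord[1])^2 + (ctr[, "y"] - coord[2])^2
  near <- has[order(d2)][seq_len(min(k, length(has)))]
  d2 <- d2[order(d2)][seq_along(near)]
  w <- exp(-d2 / (2 * bandwidth_px^2))
  if (sum(w) == 0) w <- rep(1, length(w))   # far-field: unweighted mean
  profiles <- t(vapply(near, function(s)
    decomposed[[s]]$U[type, ] / n_st[s, type],
    numeric(ncol(decomposed[[1]]$U))))
  as.vector(colSums(profiles * (w / sum(w))))
}

#' Export the typed whole-slide nucleus table (pseudo-single-cell image)
#'
#' Writes one row per nucleus (id, x, y, spot or out-spot, type,
#' provenance) and optionally a rendered scatter overlay.
#'
#' @param nuclei fully typed nucleus_set.
#' @param out_csv output CSV path.
#' @param palette optional named color vector covering every type (only
#'   needed for rendering).
#' @param out_png optional PNG path for a colored scatter of the slide.
#' @return invisibly, the CSV path.
#' @export
export_pseudo_image <- function(nuclei, out_csv, palette = NULL,
                                out_png = NULL) {
  if (anyNA(nuclei$assigned_type))
    stop(sum(is.na(nuclei$assigned_type)), " untyped nuclei")
  df <- data.frame(nucleus_id = nuclei$nucleus_id, x = nuclei$x,
                   y = nuclei$y,
                   assigned_spot = nuclei$assigned_spot,
                   assigned_type = nuclei$assigned_type,
                   provenance = ifelse(is.na(nuclei$assigned_spot),
                                       "imputed", "decomposed"),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, out_csv, row.names = FALSE)
  if (!is.null(out_png)) {
    types <- unique(df$assigned_type)
    if (is.null(palette))
      palette <- stats::setNames(grDevices::hcl.colors(length(types),
                                                       "Dark 3"), types)
    missing <- setdiff(types, names(palette))
    if (length(missing) > 0)
      stop("palette missing type(s): ", paste(missing, collapse = ", "))
    grDevices::png(out_png, width = 900, height = 900)
    on.exit(grDevices::dev.off())
    plot(df$x, -df$y, col = palette[df$assigned_type], pch = 16,
         cex = 0.6, asp = 1, xlab = "x (px)", ylab = "-y (px)",
         main = "pseudo-single-cell slide")
    graphics::legend("topright", legend = names(palette),
                     col = palette, pch = 16, cex = 0.8)
  }
  invisible(out_csv)
}
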