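# Synthetic ST generator: known per-spot cell-type counts on a grid,
# nuclei scattered inside and outside spots, spot counts formed by sampling
# annotated scRNA cells, and three corruption operators (batch effects,
# artificial zeros, multiplicative noise) at three severity levels.

noise_presets <- list(
  none   = c(sigma_r = 0,   pi_0 = 0,    sigma_n = 0),
  small  = c(sigma_r = 0.1, pi_0 = 0.05, sigma_n = 0.05),
  medium = c(sigma_r = 0.3, pi_0 = 0.10, sigma_n = 0.10),
  large  = c(sigma_r = 0.5, pi_0 = 0.20, sigma_n = 0.20)
)

# Hexagonal spot grid roughly square in extent; Visium-like scale:
# 100 um center pitch, 55 um spot diameter, 0.75 um/px.
hex_grid_geometry <- function(S, pitch_um = 100, diameter_um = 55,
                              microns_per_px = 0.75) {
  ncol_ <- ceiling(sqrt(S))
  nrow_ <- ceiling(S / ncol_)
  pitch <- pitch_um / microns_per_px
  ij <- expand.grid(col = seq_len(ncol_), row = seq_len(nrow_))
  ij <- ij[seq_len(S), ]
  x <- (ij$col - 1) * pitch + ifelse(ij$row %% 2 == 0, pitch / 2, 0) + pitch
  y <- (ij$row - 1) * pitch * sqrt(3) / 2 + pitch
  spot_geometry(sprintf("spot%03d", seq_len(S)), cbind(x = x, y = y),
                spot_diameter_px = diameter_um / microns_per_px,
                microns_per_px = microns_per_px)
}

#' Generate a ground-truth spatial composition pattern
#'
#' Builds a hexagonal spot grid, draws per-spot integer cell-type counts
#' according to a spatial pattern, and scatters nuclei: one per cell inside
#' its spot (uniform in the disc) plus out-spot nuclei at a configurable
#' density in the gaps.
#'
#' Patterns: `"uniform"` (every spot's expected composition is equal across
#' types), `"blocks"` (contiguous column blocks each restricted to an
#' overlapping subset of types), `"gaussian-bumps"` (each type's intensity
#' is a smooth spatial bump, giving gradually varying proportions).
#'
#' @param S number of spots (>= 4).
#' @param T_types number of cell types.
#' @param pattern one of uniform / blocks / gaussian-bumps.
#' @param seed integer seed.
#' @param mean_cells mean cells per spot (Poisson, min 1); default 6,
#'   typical of Visium tissue.
#' @param out_density expected out-spot nuclei per spot area of slide
#'   not covered by spots, expressed as a fraction of in-spot nucleus
#'   count; default 0.5.
#' @param type_ids optional type names.
#' @return list(geometry, nuclei (typed truth in `assigned_type`),
#'   n_st (S x T integer matrix), P_true (realized n_st / N_s),
#'   P_expected (the smooth pattern field the counts were drawn from),
#'   N_s).
#' @export
generate_truth_pattern <- function(S, T_types, pattern = c("uniform",
                                                           "blocks",
                                                           "gaussian-bumps"),
                                   seed = 1L, mean_cells = 6,
                                   out_density = 0.5, type_ids = NULL) {
  pattern <- match.arg(pattern)
  if (S < 4) stop("need at least 4 spots")
  set.seed(seed)
  geometry <- hex_grid_geometry(S)
  types <- type_ids %||% sprintf("type%d", seq_len(T_types))
  ctr <- geometry$centers

  weightf <- switch(pattern,
    uniform = function(s) rep(1, T_types),
    blocks = {
      nb <- min(2, T_types - 1)
      xb <- stats::quantile(ctr[, "x"], probs = seq(0, 1, length.out = nb + 1))
      function(s) {
        b <- findInterval(ctr[s, "x"], xb, rightmost.closed = TRUE)
        w <- rep(0, T_types)
        # overlapping type subsets, e.g. block 1 -> {1,2}, block 2 -> {2,3}
        span <- min(2, T_types)
        w[((b - 1) + seq_len(span) - 1) %% T_types + 1] <- 1
        w
      }
    },
    `gaussian-bumps` = {
      cx <- stats::runif(T_types, min(ctr[, "x"]), max(ctr[, "x"]))
      cy <- stats::runif(T_types, min(ctr[, "y"]), max(ctr[, "y"]))
      bw <- (max(ctr[, "x"]) - min(ctr[, "x"])) / 3 + 1
      function(s) {
        0.1 + exp(-((ctr[s, "x"] - cx)^2 + (ctr[s, "y"] - cy)^2) /
                    (2 * bw^2))
      }
    })

  n_st <- matrix(0L, S, T_types,
                 dimnames = list(geometry$spot_ids, types))
  P_expected <- matrix(0, S, T_types,
                       dimnames = list(geometry$spot_ids, types))
  for (s in seq_len(S)) {
    N <- max(1L, stats::rpois(1, mean_cells))
    w <- weightf(s)
    P_expected[s, ] <- w / sum(w)
    n_st[s, ] <- as.integer(stats::rmultinom(1, N, w / sum(w)))
  }
  N_s <- rowSums(n_st)

  # nuclei: one per in-spot cell, uniform inside the disc, typed by truth
  r <- geometry$spot_diameter_px / 2
  total_in <- sum(N_s)
  ang <- stats::runif(total_in, 0, 2 * pi)
  rad <- r * sqrt(stats::runif(total_in)) * 0.999
  spot_of <- rep(geometry$spot_ids, N_s)
  type_of <- unlist(lapply(seq_len(S), function(s)
    rep(types, n_st[s, ])), use.names = FALSE)
  cx <- ctr[spot_of, "x"] + rad * cos(ang)
  cy <- ctr[spot_of, "y"] + rad * sin(ang)

  n_out <- stats::rpois(1, out_density * total_in)
  ox <- stats::runif(n_out, min(ctr[, "x"]) - r, max(ctr[, "x"]) + r)
  oy <- stats::runif(n_out, min(ctr[, "y"]) - r, max(ctr[, "y"]) + r)
  # keep only nuclei genuinely outside every spot
  keep <- vapply(seq_len(n_out), function(i)
    all((ox[i] - ctr[, "x"])^2 + (oy[i] - ctr[, "y"])^2 > r^2), logical(1))
  ox <- ox[keep]; oy <- oy[keep]

  nuclei <- nucleus_set(
    sprintf("nuc%05d", seq_len(total_in + length(ox))),
    rbind(cbind(cx, cy), cbind(ox, oy)),
    assigned_spot = c(spot_of, rep(NA_character_, length(ox))),
    assigned_type = c(type_of, rep(NA_character_, length(ox))))

  P_true <- n_st / pmax(N_s, 1)
  list(geometry = geometry, nuclei = nuclei, n_st = n_st,
       P_true = P_true, P_expected = P_expected, N_s = N_s)
}

#' Simulate spot-level ST counts from an annotated scRNA reference
#'
#' For each spot, samples n_st cells of each type with replacement from the
#' reference and sums their raw counts, then applies in order: (1) gene-wise
#' batch effects, multiplying gene g by 2^(r_g) with r_g ~ Normal(0,
#' sigma_r); (2) artificial zeros, dropping each nonzero entry with
#' probability pi_0; (3) multiplicative log-normal noise with sdlog
#' sigma_n; finally rounding to integers. Severity presets (sigma_r, pi_0,
#' sigma_n): small = (0.1, 0.05, 0.05), medium = (0.3, 0.10, 0.10), large =
#' (0.5, 0.20, 0.20); `"none"` skips all corruption, making each spot row
#' the exact integer sum of its sampled cells.
#'
#' @param Y raw annotated_counts with labels.
#' @param truth output of [generate_truth_pattern()] (uses `n_st`).
#' @param noise_level none / small / medium / large, or a named numeric
#'   vector `c(sigma_r=, pi_0=, sigma_n=)`.
#' @param seed integer seed.
#' @return list of class `simulation_result`: `X_sim` (annotated_counts),
#'   `truth` holding `n_st`, `P_true`, `sampled_cells` (per-spot character
#'   list), planted `r`, the corruption parameters, and the seed.
#' @export
simulate_spots <- function(Y, truth, noise_level = "none", seed = 1L) {
  stopifnot(inherits(Y, "annotated_counts"))
  if (is.null(Y$labels)) stop("reference must carry cell-type labels")
  if (!identical(Y$normalized, "raw"))
    stop("simulation samples raw counts")
  pars <- if (is.character(noise_level)) {
    if (!noise_level %in% names(noise_presets))
      stop("unknown noise level: ", noise_level)
    noise_presets[[noise_level]]
  } else noise_level
  n_st <- truth$n_st
  types <- colnames(n_st)
  absent <- setdiff(types[colSums(n_st) > 0], unique(Y$labels))
  if (length(absent) > 0)
    stop("truth references type(s) absent from reference: ",
         paste(absent, collapse = ", "))
  set.seed(seed)
  S <- nrow(n_st); G <- ncol(Y$matrix)
  by_type <- split(seq_len(nrow(Y$matrix)), Y$labels)
  X <- matrix(0, S, G, dimnames = list(rownames(n_st),
                                       colnames(Y$matrix)))
  sampled <- vector("list", S)
  names(sampled) <- rownames(n_st)
  for (s in seq_len(S)) {
    picks <- integer(0)
    for (t in types[n_st[s, ] > 0]) {
      pool <- by_type[[t]]
      picks <- c(picks, pool[sample.int(length(pool), n_st[s, t],
                                        replace = TRUE)])
    }
    sampled[[s]] <- rownames(Y$matrix)[picks]
    if (length(picks) > 0)
      X[s, ] <- colSums(Y$matrix[picks, , drop = FALSE])
  }

  r <- numeric(G)
  if (pars[["sigma_r"]] > 0) {
    r <- stats::rnorm(G, 0, pars[["sigma_r"]])
    X <- sweep(X, 2, 2^r, "*")
  }
  if (pars[["pi_0"]] > 0) {
    nz <- which(X > 0)
    drop <- nz[stats::runif(length(nz)) < pars[["pi_0"]]]
    X[drop] <- 0
  }
  if (pars[["sigma_n"]] > 0) {
    X <- X * stats::rlnorm(length(X), 0, pars[["sigma_n"]])
  }
  if (any(pars > 0)) X <- round(X)

  structure(list(
    X_sim = annotated_counts(X),
    truth = list(n_st = n_st, P_true = truth$P_true,
                 sampled_cells = sampled, r = r,
                 params = pars, noise_level = if (is.character(noise_level))
                   noise_level else "custom",
                 seed = seed)),
    class = "simulation_result")
}

#' Write a simulated dataset to disk in the standard on-disk dialects
#'
#' Emits the count matrix (Matrix Market + id lists), Visium-style
#' positions CSV and scalefactors JSON, the nuclei CSV, and truth tables
#' (n_st CSV, planted r CSV, sampled-cell manifest CSV).
#'
#' @param sim simulation_result.
#' @param truth output of [generate_truth_pattern()] (geometry + nuclei).
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_simulation <- function(sim, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts(sim$X_sim, dir, prefix = "st")
  g <- truth$geometry
  utils::write.csv(
    data.frame(barcode = g$spot_ids,
               in_tissue = as.integer(g$in_tissue),
               array_row = 0L, array_col = 0L,
               pxl_row_in_fullres = g$centers[, "y"],
               pxl_col_in_fullres = g$centers[, "x"]),
    file.path(dir, "tissue_positions.csv"), row.names = FALSE)
  jsonlite::write_json(list(spot_diameter_fullres = g$spot_diameter_px,
                            microns_per_pixel = g$microns_per_px),
                       file.path(dir, "scalefactors_json.json"),
                       auto_unbox = TRUE, digits = NA)
  write_nuclei(truth$nuclei, file.path(dir, "nuclei.csv"))
  utils::write.csv(data.frame(spot = rownames(sim$truth$n_st),
                              sim$truth$n_st, check.names = FALSE),
                   file.path(dir, "truth_n_st.csv"), row.names = FALSE)
  utils::write.csv(data.frame(gene = colnames(sim$X_sim$matrix),
                              r = sim$truth$r),
                   file.path(dir, "truth_r.csv"), row.names = FALSE)
  manifest <- data.frame(
    spot = rep(names(sim$truth$sampled_cells),
               lengths(sim$truth$sampled_cells)),
    cell = unlist(sim$truth$sampled_cells, use.names = FALSE))
  utils::write.csv(manifest, file.path(dir, "truth_sampled_cells.csv"),
                   row.names = FALSE)
  invisible(dir)
}
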