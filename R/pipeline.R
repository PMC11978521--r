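# End-to-end orchestration: reference -> assignment -> deconvolution ->
# decomposition -> imputation -> export, with per-stage seeds derived
# deterministically from one master seed.

stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h) %% .Machine$integer.max)
}

#' Run the full pipeline on in-memory inputs
#'
#' Executes the five stages in order: (1) marker selection and signature
#' construction from the scRNA reference; (2) nucleus-to-spot assignment;
#' (3) generative-model fitting on marker-gene spot counts; (4) update of
#' proportions to integer cell counts (or threshold-only in image-free
#' mode) and decomposition of all genes into per-cell profiles; (5) GP
#' imputation and typing of out-spot nuclei. All stochastic stages draw
#' their seeds from `config$seed` via stage-name hashes, so a rerun is
#' byte-identical.
#'
#' @param st raw annotated_counts of spot counts.
#' @param scrna raw annotated_counts with cell-type labels.
#' @param geometry spot_geometry aligned to `st` rows.
#' @param nuclei optional nucleus_set; when NULL the image-free branch
#'   thresholds proportions with `config$l_p` and skips per-cell output.
#' @param config pipeline_config.
#' @param out_dir optional directory; stage outputs are written when set.
#' @param cell_mode per-cell partition mode, `"expected"` or `"sampled"`.
#' @return list of class `pipeline_result` with `signature`, `markers`,
#'   `deconvolution`, `P`, `P_tilde`, `n_st` (image branch), `cells`,
#'   `nuclei`, `field`, and `manifest` (config snapshot, seeds, stage
#'   outputs).
#' @export
run_pipeline <- function(st, scrna, geometry, nuclei = NULL,
                         config = pipeline_config(), out_dir = NULL,
                         cell_mode = c("expected", "sampled")) {
  cell_mode <- match.arg(cell_mode)
  shared <- intersect_genes(st, scrna)
  st <- shared$x; scrna <- shared$y

  # stage 1: reference
  scrna_cpm <- cpm_normalize(scrna)
  sel <- select_markers(scrna_cpm, config)
  sig_m <- build_signature(scrna_cpm, gene_subset = sel$markers)
  sig_full <- build_signature(scrna_cpm)

  # stage 2: segmentation-derived assignment (optional)
  assignment <- NULL
  if (!is.null(nuclei)) assignment <- assign_nuclei_to_spots(nuclei, geometry)

  # stage 3: generative model on marker genes
  X_m <- st$matrix[, sel$markers, drop = FALSE]
  cfg_fit <- config
  cfg_fit$seed <- stage_seed(config$seed, "deconvolution")
  fit <- fit_deconvolution(X_m, sig_m, cfg_fit)

  # stage 4: update proportions and decompose
  S <- nrow(fit$P)
  types <- colnames(fit$P)
  if (!is.null(assignment)) {
    n_st <- t(vapply(seq_len(S), function(s)
      apportion_cells(fit$P[s, ], assignment$N_s[rownames(fit$P)[s]]),
      integer(length(types))))
    dimnames(n_st) <- dimnames(fit$P)
    N_s <- rowSums(n_st)
    P_tilde <- n_st / pmax(N_s, 1)
    P_tilde[N_s == 0, ] <- fit$P[N_s == 0, , drop = FALSE]
  } else {
    n_st <- NULL
    P_tilde <- t(apply(fit$P, 1, threshold_proportions, l_p = config$l_p))
    dimnames(P_tilde) <- dimnames(fit$P)
  }
  decomposed <- decompose_all(st, P_tilde, sig_full)

  cells <- NULL
  if (!is.null(assignment)) {
    nuc <- annotate_in_spot_nuclei(assignment$nuclei, n_st,
                                   seed = stage_seed(config$seed,
                                                     "annotate"))
    cells <- build_cell_profiles(decomposed, nuc, n_st, mode = cell_mode,
                                 seed = stage_seed(config$seed,
                                                   "partition"))
  } else nuc <- NULL

  # stage 5: imputation for out-spot nuclei
  field <- NULL
  if (nrow(geometry$centers) >= 10) {
    field <- fit_proportion_field(geometry, P_tilde, config)
    if (!is.null(nuc) && any(is.na(nuc$assigned_spot))) {
      nuc <- annotate_out_spot_nuclei(nuc, field,
                                      seed = stage_seed(config$seed,
                                                        "impute"))
    }
  }

  manifest <- list(config = unclass(config),
                   seeds = list(
                     deconvolution = stage_seed(config$seed, "deconvolution"),
                     annotate = stage_seed(config$seed, "annotate"),
                     partition = stage_seed(config$seed, "partition"),
                     impute = stage_seed(config$seed, "impute")),
                   n_markers = length(sel$markers),
                   version = as.character(utils::packageVersion("spotdecon")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_signature(sig_m, file.path(out_dir, "signature_markers.csv"))
    utils::write.csv(data.frame(spot = rownames(fit$P), fit$P,
                                check.names = FALSE),
                     file.path(out_dir, "proportions.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(gene = names(fit$r), r = fit$r),
                     file.path(out_dir, "batch_effects.csv"),
                     row.names = FALSE)
    if (!is.null(cells)) write_cell_profiles(cells, out_dir)
    if (!is.null(nuc)) write_nuclei(nuc, file.path(out_dir, "nuclei.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$out_dir <- out_dir
  }

  structure(list(signature = sig_full, signature_markers = sig_m,
                 markers = sel, deconvolution = fit, P = fit$P,
                 P_tilde = P_tilde, n_st = n_st, decomposed = decomposed,
                 cells = cells, nuclei = nuc, field = field,
                 manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d spots x %d types, %d marker genes%s\n",
              nrow(x$P), ncol(x$P), x$manifest$n_markers,
              if (is.null(x$cells)) " (image-free branch)" else
                sprintf(", %d cells", nrow(x$cells$expression))))
  invisible(x)
}
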