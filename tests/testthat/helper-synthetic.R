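# Synthetic annotated scRNA references with planted per-type markers.
# Cells are Poisson draws around a per-type rate profile; a block of
# `markers_per_type` genes per type is elevated `elevation`-fold, mimicking
# strong discriminative markers; library sizes vary across cells.
make_scrna <- function(T_types = 5, cells_per_type = 40, G = 500,
                       markers_per_type = 40, elevation = 8, depth = 5,
                       seed = 1) {
  set.seed(seed)
  types <- sprintf("type%d", seq_len(T_types))
  base <- matrix(rgamma(T_types * G, shape = 2, rate = 2), T_types, G)
  for (t in seq_len(T_types)) {
    idx <- ((t - 1) * markers_per_type + 1):(t * markers_per_type)
    base[t, idx] <- base[t, idx] * elevation
  }
  labels <- rep(types, each = cells_per_type)
  libsize <- rlnorm(length(labels), 0, 0.3)
  m <- t(vapply(seq_along(labels), function(i) {
    rate <- base[match(labels[i], types), ] * depth * libsize[i]
    rpois(G, rate)
  }, numeric(G)))
  rownames(m) <- sprintf("cell%04d", seq_along(labels))
  colnames(m) <- sprintf("gene%04d", seq_len(G))
  annotated_counts(m, labels = labels)
}

# Random simplex rows.
random_simplex <- function(n, T_types) {
  x <- matrix(rgamma(n * T_types, 1, 1), n, T_types)
  x / rowSums(x)
}

# Reference (markers + signatures) prepared once from a synthetic scRNA.
make_reference <- function(sc, config = spotdecon::pipeline_config()) {
  cpm <- spotdecon::cpm_normalize(sc)
  sel <- spotdecon::select_markers(cpm, config)
  list(cpm = cpm, sel = sel,
       sig_m = spotdecon::build_signature(cpm, gene_subset = sel$markers),
       sig_full = spotdecon::build_signature(cpm))
}
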