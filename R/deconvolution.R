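# Multinomial generative model of spot counts over marker genes.
#
# x_s^(m) | Q, r, Phi ~ Multinomial(m'_s, rho~_s), with
#   rho_sg   = sum_t q_st * phi_tg          (gene mixture from contributions)
#   rho~_sg  = rho_sg 2^{r_g} / sum_g' rho_sg' 2^{r_g'}   (batch adjustment)
# Q rows live on the simplex (gene-contribution scores), r_g is a per-gene
# log2 batch factor shared across spots. Estimation is MAP under a flat
# Dirichlet(1) prior on Q rows and Normal(0, 1) prior on r, by Adam on the
# softmax parameterization of Q; the likelihood is shift-invariant in r, so
# the reported r is centered to mean zero.

#' Gene mixture implied by contribution scores
#'
#' @param Q S x T matrix with unit row sums.
#' @param phi_m signature_matrix or bare T x G matrix with unit row sums.
#' @return S x G matrix `rho` with unit row sums.
#' @export
compute_rho <- function(Q, phi_m) {
  phi <- if (inherits(phi_m, "signature_matrix")) phi_m$phi else phi_m
  if (ncol(Q) != nrow(phi))
    stop("Q columns (", ncol(Q), ") must match signature types (",
         nrow(phi), ")")
  Q %*% phi
}

#' Apply gene-wise batch effects to a gene mixture
#'
#' Multiplies gene g by 2^(r_g) and renormalizes each row; invariant to a
#' constant shift of r.
#'
#' @param rho S x G matrix with positive row sums.
#' @param r length-G numeric vector (log2 scale).
#' @return S x G row-normalized matrix.
#' @export
apply_batch_effect <- function(rho, r) {
  if (any(!is.finite(r))) stop("non-finite batch-effect parameters")
  if (length(r) != ncol(rho)) stop("r length must equal gene count")
  w <- 2^(r - mean(r))              # center for numerical stability
  num <- sweep(rho, 2, w, "*")
  d <- rowSums(num)
  if (any(d == 0)) stop("row(s) of rho are entirely zero")
  num / d
}

row_softmax <- function(A) {
  e <- exp(A - apply(A, 1, max))
  e / rowSums(e)
}

#' Fit the deconvolution model
#'
#' Maximum a posteriori estimation of contribution scores Q and batch
#' effects r from raw spot counts over marker genes, by Adam on the exact
#' gradient of the multinomial log posterior. Deterministic given the
#' configuration (initialization is at the uniform simplex and r = 0).
#' Spots with zero total counts are excluded from the likelihood and given
#' uniform proportions with a warning.
#'
#' @param X_m annotated_counts (raw) or matrix of spot counts restricted to
#'   the signature's marker genes (columns must match `phi_m$gene_ids`).
#' @param phi_m signature_matrix over the marker genes.
#' @param config pipeline_config; `n_iterations`, `learning_rate`, `seed`
#'   are used.
#' @param estimate_batch fit r (TRUE) or hold it at zero.
#' @param sigma_r prior standard deviation of r.
#' @param qp_mode conversion of Q to cell-number proportions, see
#'   [contribution_to_proportion()].
#' @return object of class `deconvolution_result`: list(Q, r, P,
#'   loss_trace, seed, n_iterations).
#' @export
fit_deconvolution <- function(X_m, phi_m, config = pipeline_config(),
                              estimate_batch = TRUE, sigma_r = 1,
                              qp_mode = c("mrna", "identity")) {
  qp_mode <- match.arg(qp_mode)
  X <- if (inherits(X_m, "annotated_counts")) X_m$matrix else X_m
  if (any(X < 0)) stop("negative entries in spot counts")
  if (any(abs(X - round(X)) > 1e-8))
    stop("spot counts must be integers (raw counts)")
  stopifnot(inherits(phi_m, "signature_matrix"))
  phi <- phi_m$phi
  if (!is.null(colnames(X))) {
    if (!all(colnames(X) == phi_m$gene_ids)) {
      if (!all(phi_m$gene_ids %in% colnames(X)))
        stop("spot matrix lacks signature genes")
      X <- X[, phi_m$gene_ids, drop = FALSE]
    }
  } else if (ncol(X) != ncol(phi)) stop("gene dimension mismatch")

  S <- nrow(X); Tn <- nrow(phi); G <- ncol(phi)
  msum <- rowSums(X)
  live <- msum > 0
  if (!all(live))
    warning(sum(!live), " spot(s) with zero counts excluded from the fit")
  Xl <- X[live, , drop = FALSE]
  ml <- msum[live]
  colsum <- colSums(Xl)

  set.seed(config$seed)
  A <- matrix(0, sum(live), Tn)       # softmax logits of Q
  r <- numeric(G)
  log2c <- log(2)
  eps <- 1e-12

  adam <- function() list(m = 0, v = 0, t = 0)
  stA <- adam(); str_ <- adam()
  b1 <- 0.9; b2 <- 0.999; ae <- 1e-8
  lr <- config$learning_rate
  loss_trace <- numeric(config$n_iterations)

  for (it in seq_len(config$n_iterations)) {
    Q <- row_softmax(A)
    rho <- Q %*% phi
    w <- 2^r
    dw <- as.vector(rho %*% w)                 # per-spot normalizer
    # log posterior (dropping constants)
    ll <- sum(Xl * log(rho + eps)) + log2c * sum(r * colsum) -
      sum(ml * log(dw)) - sum(r^2) / (2 * sigma_r^2)
    loss_trace[it] <- -ll

    # gradients
    Grho <- Xl / (rho + eps) - outer(ml / dw, w)   # d ll / d rho
    GQ <- Grho %*% t(phi)
    GA <- Q * (GQ - rowSums(Q * GQ))
    stA$t <- stA$t + 1
    stA$m <- b1 * stA$m + (1 - b1) * GA
    stA$v <- b2 * stA$v + (1 - b2) * GA^2
    A <- A + lr * (stA$m / (1 - b1^stA$t)) /
      (sqrt(stA$v / (1 - b2^stA$t)) + ae)

    if (estimate_batch) {
      Gr <- log2c * (colsum - w * as.vector(crossprod(rho, ml / dw))) -
        r / sigma_r^2
      str_$t <- str_$t + 1
      str_$m <- b1 * str_$m + (1 - b1) * Gr
      str_$v <- b2 * str_$v + (1 - b2) * Gr^2
      r <- r + lr * (str_$m / (1 - b1^str_$t)) /
        (sqrt(str_$v / (1 - b2^str_$t)) + ae)
    }
    if (!is.finite(loss_trace[it]))
      stop("divergent loss at iteration ", it,
           "; last losses: ",
           paste(utils::tail(round(loss_trace[seq_len(it)], 3), 5),
                 collapse = ", "))
  }

  Qfull <- matrix(1 / Tn, S, Tn)
  Qfull[live, ] <- row_softmax(A)
  rownames(Qfull) <- rownames(X)
  colnames(Qfull) <- phi_m$type_ids
  r <- r - mean(r)
  names(r) <- phi_m$gene_ids
  P <- contribution_to_proportion(Qfull, phi_m$nu, mode = qp_mode)
  structure(list(Q = Qfull, r = r, P = P, loss_trace = loss_trace,
                 seed = config$seed, n_iterations = config$n_iterations),
            class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf("deconvolution_result: %d spots x %d types, %d iterations, final loss %.4g\n",
              nrow(x$Q), ncol(x$Q), x$n_iterations,
              utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' Convert gene-contribution scores to cell-number proportions
#'
#' Gene contribution and cell-number share differ when cell types differ in
#' mRNA content: mode `"mrna"` divides each contribution by the type's mean
#' library size `nu` and renormalizes; mode `"identity"` returns Q.
#'
#' @param Q S x T contribution matrix with unit row sums.
#' @param nu positive per-type mean library sizes.
#' @param mode `"mrna"` (default) or `"identity"`.
#' @return S x T proportion matrix with unit row sums.
#' @export
contribution_to_proportion <- function(Q, nu, mode = c("mrna", "identity")) {
  mode <- match.arg(mode)
  if (mode == "identity") return(Q)
  if (any(nu <= 0)) stop("nu must be positive")
  P <- sweep(Q, 2, nu, "/")
  P / rowSums(P)
}
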