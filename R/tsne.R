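## Exact O(n^2) t-SNE, written directly from the defining equations: Gaussian
## conditional affinities with per-point bandwidths tuned to a target
## perplexity, symmetrised joint affinities, Student-t low-dimensional
## affinities, and KL-divergence gradient descent with early exaggeration.

sq_dists <- function(X) {
  s <- rowSums(X^2)
  D <- outer(s, s, "+") - 2 * tcrossprod(X)
  D[D < 0] <- 0
  diag(D) <- 0
  D
}

## Shannon entropy (bits) and probabilities of row i at precision beta = 1/(2 sigma^2).
## Distances are shifted by their minimum before exponentiation so large beta
## cannot underflow every weight.
row_affinity <- function(d2_row, beta) {
  p <- exp(-(d2_row - min(d2_row)) * beta)
  sp <- sum(p)
  if (sp <= 0) return(list(H = 0, p = p))
  p <- p / sp
  nz <- p > 0
  list(H = -sum(p[nz] * log2(p[nz])), p = p)
}

#' Conditional Gaussian affinities at a target perplexity
#'
#' For every point the Gaussian bandwidth `sigma_i` is found by bisection so
#' that the perplexity `2^H(p_.|i)` of its conditional distribution matches
#' the target within `tol`. Self-affinities are zero and each row sums to 1.
#'
#' @param X numeric matrix (rows = points).
#' @param perplexity target perplexity (effective neighbour count), < n.
#' @param tol bisection tolerance on the achieved perplexity.
#' @param max_iter maximum bisection steps per point.
#' @return A list with `P_cond` (row-stochastic matrix), `sigmas`, and the
#'   `perplexity` used.
#' @export
conditional_affinities <- function(X, perplexity = 30, tol = 1e-4,
                                   max_iter = 200) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 3)
  if (perplexity >= n) stop("perplexity must be below the number of points",
                            call. = FALSE)
  D2 <- sq_dists(X)
  if (any(D2[upper.tri(D2)] == 0)) {
    warning("duplicate points detected; adding tiny jitter to their distances")
    D2[D2 == 0 & upper.tri(D2)] <- 1e-12
    D2[lower.tri(D2)] <- t(D2)[lower.tri(D2)]
  }
  ## snap distances equal to 1e-9 relative precision: round-off asymmetries
  ## between truly equidistant points would otherwise be amplified by the
  ## bandwidth search when the target perplexity is close to unattainable
  s <- max(D2)
  if (s > 0) D2 <- round(D2 / s, 9) * s
  target <- log2(perplexity)
  P <- matrix(0, n, n)
  sigmas <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- D2[i, -i]
    lo <- 0
    hi <- Inf
    beta <- 1
    res <- NULL
    for (it in seq_len(max_iter)) {
      res <- row_affinity(d2, beta)
      diff <- res$H - target
      if (abs(2^res$H - perplexity) < tol) break
      if (diff > 0) {            # entropy too high -> narrow the kernel
        lo <- beta
        beta <- if (is.finite(hi)) (lo + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- (lo + hi) / 2
      }
    }
    P[i, -i] <- res$p
    sigmas[i] <- sqrt(1 / (2 * beta))
  }
  list(P_cond = P, sigmas = sigmas, perplexity = perplexity)
}

#' Symmetrised joint affinities
#'
#' `p_ij = (p_{j|i} + p_{i|j}) / (2n)`; the result is symmetric, non-negative
#' and sums to 1.
#'
#' @param P_cond row-stochastic conditional affinity matrix.
#' @return Symmetric joint probability matrix.
#' @export
symmetrize_affinities <- function(P_cond) {
  n <- nrow(P_cond)
  (P_cond + t(P_cond)) / (2 * n)
}

#' Student-t low-dimensional affinities
#'
#' `q_ij = (1 + ||y_i - y_j||^2)^{-1}` normalised over all ordered pairs,
#' diagonal zero.
#'
#' @param Y numeric matrix of embedding coordinates.
#' @return Joint probability matrix Q.
#' @export
q_affinities <- function(Y) {
  W <- 1 / (1 + sq_dists(as.matrix(Y)))
  diag(W) <- 0
  W / sum(W)
}

#' Kullback-Leibler cost between affinity matrices
#'
#' `C = sum p_ij log(p_ij / q_ij)` with the convention `0 log 0 = 0`.
#'
#' @param P,Q matching probability matrices.
#' @return The (non-negative) divergence.
#' @export
kl_cost <- function(P, Q) {
  stopifnot(all(dim(P) == dim(Q)))
  pos <- P > 0
  if (any(Q[pos] == 0)) stop("zero low-dimensional affinity at positive p_ij",
                             call. = FALSE)
  sum(P[pos] * log(P[pos] / Q[pos]))
}

## Analytic KL gradient: dC/dy_i = 4 sum_j (p_ij - q_ij) w_ij (y_i - y_j),
## with w_ij the unnormalised Student-t weight.
tsne_gradient <- function(P, Y) {
  W <- 1 / (1 + sq_dists(Y))
  diag(W) <- 0
  Q <- W / sum(W)
  M <- (P - Q) * W
  4 * (diag(rowSums(M)) %*% Y - M %*% Y)
}

#' t-SNE embedding by momentum gradient descent
#'
#' Canonical schedule: Gaussian initialisation (sd 1e-4), early exaggeration
#' of the joint affinities for the first `exaggeration_iter` iterations,
#' momentum switching from 0.5 to 0.8, and per-coordinate adaptive gains.
#' Feature columns are expected to be standardised beforehand (the pipeline
#' z-scores them); distances are plain Euclidean.
#'
#' @param X numeric matrix of (standardised) features, n >= 10 rows.
#' @param dims embedding dimensionality (default 3).
#' @param perplexity target perplexity; capped at `(n - 1) / 3` for tiny
#'   inputs.
#' @param learning_rate gradient-descent step size.
#' @param n_iter total iterations.
#' @param seed integer seed for the initial coordinates.
#' @param exaggeration early-exaggeration factor applied to P.
#' @param exaggeration_iter iterations of the exaggeration phase.
#' @param verbose print the cost every 100 iterations.
#' @return A list of class `tsne_embedding`: `Y` (n x dims), `cost_trace`,
#'   `perplexity`, `seed`.
#' @export
tsne_embed <- function(X, dims = 3, perplexity = 30, learning_rate = 200,
                       n_iter = 1000, seed = 1L, exaggeration = 12,
                       exaggeration_iter = 250, verbose = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 10)
  perplexity <- min(perplexity, (n - 1) / 3)
  aff <- conditional_affinities(X, perplexity)
  P <- symmetrize_affinities(aff$P_cond)

  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  Y <- matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
  V <- matrix(0, n, dims)
  gains <- matrix(1, n, dims)
  cost_trace <- numeric(n_iter)
  prev_cost <- Inf
  for (it in seq_len(n_iter)) {
    if (it == exaggeration_iter + 1L) {
      ## the objective changes when exaggeration ends; drop the old momentum
      V[] <- 0
      gains[] <- 1
    }
    Pg <- if (it <= exaggeration_iter) exaggeration * P else P
    G <- tsne_gradient(Pg, Y)
    mom <- if (it <= exaggeration_iter) 0.5 else 0.8
    gains <- ifelse(sign(G) != sign(V), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    V <- mom * V - learning_rate * gains * G
    cand <- sweep(Y + V, 2, colMeans(Y + V))
    cost <- kl_cost(P, q_affinities(cand))
    ## monotone safeguard: outside the exaggeration phase, halve the step
    ## until the true KL does not increase (momentum can overshoot badly on
    ## small problems right after the objective switches back)
    if (it > exaggeration_iter + 1L) {
      tries <- 0L
      while (is.finite(prev_cost) && cost > prev_cost + 1e-9 && tries < 12L) {
        V <- V / 2
        cand <- sweep(Y + V, 2, colMeans(Y + V))
        cost <- kl_cost(P, q_affinities(cand))
        tries <- tries + 1L
      }
    }
    Y <- cand
    cost_trace[it] <- cost
    prev_cost <- cost
    if (!is.finite(cost_trace[it]))
      stop("t-SNE diverged (non-finite cost) at iteration ", it, call. = FALSE)
    if (verbose && it %% 100 == 0)
      message(sprintf("iter %d: KL = %.4f", it, cost_trace[it]))
  }
  structure(list(Y = Y, cost_trace = cost_trace, perplexity = perplexity,
                 seed = seed),
            class = "tsne_embedding")
}

#' Embed a wide feature table into 3-D
#'
#' Z-scores the feature columns (constant columns are dropped) and runs
#' [tsne_embed()]; key columns and labels are carried onto the embedding.
#'
#' @param wide a wide feature data frame from [feature_table_wide()].
#' @param ... passed to [tsne_embed()].
#' @return A data frame with keys, `y1..y3` and `label`, plus the embedding
#'   object as attribute `"embedding"`.
#' @export
embed_feature_table <- function(wide, ...) {
  keycols <- c("subject", "trial", "channel", "window", "label")
  X <- as.matrix(wide[, setdiff(names(wide), keycols), drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  X <- scale(X)
  emb <- tsne_embed(X, ...)
  out <- wide[, keycols]
  for (d in seq_len(ncol(emb$Y))) out[[paste0("y", d)]] <- emb$Y[, d]
  attr(out, "embedding") <- emb
  out
}
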