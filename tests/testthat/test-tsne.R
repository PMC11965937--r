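test_that("conditional affinities are row-stochastic at the target perplexity", {
  set.seed(51)
  X <- matrix(stats::rnorm(50 * 4), 50, 4)
  aff <- conditional_affinities(X, 15)
  expect_lt(max(abs(rowSums(aff$P_cond) - 1)), 1e-8)
  expect_true(all(diag(aff$P_cond) == 0))
  achieved <- apply(aff$P_cond, 1, function(p) {
    p <- p[p > 0]
    2^(-sum(p * log2(p)))
  })
  expect_lt(max(abs(achieved - 15)), 1e-3)

  ## three equidistant points: all off-diagonal conditionals are 1/2
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  a3 <- conditional_affinities(tri, perplexity = 1.9)
  off <- a3$P_cond[row(a3$P_cond) != col(a3$P_cond)]
  expect_equal(off, rep(0.5, 6), tolerance = 1e-9)

  expect_warning(conditional_affinities(rbind(tri, tri[1, ]), 2), "duplicate")
})

test_that("symmetrised affinities form a joint distribution", {
  set.seed(52)
  X <- matrix(stats::rnorm(12 * 3), 12, 3)
  P <- symmetrize_affinities(conditional_affinities(X, 3)$P_cond)
  expect_lt(abs(sum(P) - 1), 1e-8)
  expect_identical(P, t(P))
  expect_true(all(P >= 0))
})

test_that("low-dimensional affinities normalise and decay with distance", {
  Y2 <- matrix(c(0, 0, 0, 5), 2, 2, byrow = TRUE)
  Q2 <- q_affinities(Y2)
  expect_equal(Q2[1, 2], 0.5)
  expect_equal(Q2[2, 1], 0.5)

  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  Qt <- q_affinities(tri)
  off <- Qt[upper.tri(Qt)]
  expect_true(all(abs(off - off[1]) < 1e-12))

  set.seed(53)
  Y <- matrix(stats::rnorm(20 * 3), 20, 3)
  Q <- q_affinities(Y)
  expect_lt(abs(sum(Q) - 1), 1e-8)
  D <- as.matrix(stats::dist(Y))
  ij <- which(upper.tri(D), arr.ind = TRUE)
  ord <- order(D[upper.tri(D)])
  expect_true(all(diff(Q[upper.tri(Q)][ord]) <= 1e-15))
})

test_that("KL cost matches the double-sum oracle and the Gibbs inequality", {
  set.seed(54)
  mk <- function() {
    M <- matrix(stats::runif(25), 5, 5)
    diag(M) <- 0
    M <- (M + t(M))
    M / sum(M)
  }
  P <- mk()
  Q <- mk()
  expect_equal(kl_cost(P, P), 0)
  expect_gt(kl_cost(P, Q), 0)
  expect_lt(abs(kl_cost(P, Q) - kl_oracle(P, Q)), 1e-12)
  Qz <- Q
  Qz[1, 2] <- 0
  expect_error(kl_cost(P, Qz), "zero")
})

test_that("the analytic gradient matches central finite differences", {
  set.seed(55)
  X <- matrix(stats::rnorm(6 * 2), 6, 2)
  P <- symmetrize_affinities(conditional_affinities(X, 5 / 3)$P_cond)
  Y <- matrix(stats::rnorm(6 * 3) * 0.1, 6, 3)
  G <- emgfatigue:::tsne_gradient(P, Y)
  eps <- 1e-6
  Gfd <- Y * 0
  for (i in 1:6) for (d in 1:3) {
    Yp <- Y; Yp[i, d] <- Yp[i, d] + eps
    Ym <- Y; Ym[i, d] <- Ym[i, d] - eps
    Gfd[i, d] <- (kl_cost(P, q_affinities(Yp)) -
                    kl_cost(P, q_affinities(Ym))) / (2 * eps)
  }
  expect_lt(max(abs(G - Gfd)) / max(abs(Gfd)), 1e-4)
})

test_that("embedding is seeded-deterministic and its cost settles", {
  set.seed(56)
  X <- scale(rbind(matrix(stats::rnorm(20 * 5), 20, 5),
                   matrix(stats::rnorm(20 * 5) + 4, 20, 5)))
  e1 <- tsne_embed(X, dims = 3, perplexity = 8, n_iter = 400, seed = 9)
  e2 <- tsne_embed(X, dims = 3, perplexity = 8, n_iter = 400, seed = 9)
  expect_identical(e1$Y, e2$Y)
  expect_true(all(is.finite(e1$Y)))
  expect_true(all(e1$cost_trace >= 0))

  ## after the exaggeration phase the cost is non-increasing over 50-iteration
  ## spans (isolated upticks below 1e-3 tolerated)
  trace <- e1$cost_trace[251:400]
  spans <- seq(1, length(trace) - 50)
  expect_true(all(trace[spans + 50] <= trace[spans] + 1e-3))
  up <- diff(trace)
  expect_true(all(up[up > 0] < 1e-3))
})

test_that("well-separated clusters stay separated in 3-D", {
  expect_gt(cluster_silhouette(1), 0.8)
})
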