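# PCA baselines, affine-transformation analysis, scaling factors and
# benefit scores.

test_that("substitution-matrix PCA separates chemically similar residues", {
  emb <- pca_embedding(blosum62())
  d <- function(a, b) sqrt(sum((emb[a, ] - emb[b, ])^2))
  # leucine and isoleucine (both aliphatic) sit closer than leucine and
  # charged aspartate
  expect_lt(d("L", "I"), d("L", "D"))
  # variance captured matches an independent eigendecomposition
  B <- blosum62()
  ev <- eigen(stats::cov(B), symmetric = TRUE)$values
  captured <- sum(apply(emb, 2, stats::var)) / sum(ev)
  expect_gte(captured + 1e-12, sum(ev[1:2]) / sum(ev))
  # deterministic under the sign convention
  expect_equal(pca_embedding(blosum62()), emb)
  expect_error(pca_embedding(matrix(stats::rnorm(400), 20, 20)),
               "symmetric")
})

test_that("degenerate equal-eigenvalue input is handled deterministically", {
  I20 <- diag(20)
  dimnames(I20) <- list(AA_ALPHABET, AA_ALPHABET)
  e1 <- pca_embedding(I20)
  e2 <- pca_embedding(I20)
  expect_identical(e1, e2)
  expect_true(all(is.finite(e1)))
})

test_that("affine fits recover exact and noisy generating transforms", {
  set.seed(4)
  E_r <- matrix(stats::rnorm(40), 20, 2)

  pure_scale <- fit_affine(E_r, 2 * E_r)
  expect_equal(pure_scale$A, 2 * diag(2), tolerance = 1e-10)
  expect_equal(pure_scale$t, c(0, 0), tolerance = 1e-10)
  expect_equal(pure_scale$residual, 0, tolerance = 1e-12)

  shifted <- fit_affine(E_r, E_r + matrix(1, 20, 2))
  expect_equal(shifted$A, diag(2), tolerance = 1e-10)
  expect_equal(shifted$t, c(1, 1), tolerance = 1e-10)

  # noisy affine data: recover A within 1e-2 Frobenius at noise sd 1e-3
  A_true <- matrix(c(1.5, 0.3, -0.2, 0.8), 2, 2)
  t_true <- c(0.5, -1)
  E_m <- E_r %*% A_true + rep(1, 20) %o% t_true +
    matrix(stats::rnorm(40, sd = 1e-3), 20, 2)
  fit <- fit_affine(E_r, E_m)
  expect_lt(sqrt(sum((fit$A - A_true)^2)), 1e-2)

  expect_error(fit_affine(matrix(1, 20, 2), matrix(1, 20, 2)), "degenerate")
})

test_that("scaling factors follow the SVD closed forms", {
  expect_equal(scaling_factors(diag(c(3, 2))), c(S_x = 3, S_y = 2))
  expect_equal(scaling_factors(matrix(0, 2, 2)), c(S_x = 0, S_y = 0))
  expect_equal(scaling_factors(5 * diag(2)), c(S_x = 5, S_y = 5))
  # invariant under global sign flips (the SVD sign ambiguity)
  set.seed(6)
  A <- matrix(stats::rnorm(4), 2, 2)
  expect_equal(scaling_factors(A), scaling_factors(-A))
})

test_that("fit_affine composed with scaling_factors recovers diagonal maps", {
  set.seed(9)
  E_r <- matrix(stats::rnorm(40), 20, 2)
  for (ab in list(c(3, 2), c(-1.5, 0.4), c(0.2, 5))) {
    A <- diag(ab)
    fit <- fit_affine(E_r, E_r %*% A)
    expect_equal(unname(scaling_factors(fit$A)), abs(ab), tolerance = 1e-8)
  }
})

test_that("allele benefit scores average geometric means across positions", {
  f <- function(sx, sy) data.frame(position = 1:9, S_x = sx, S_y = sy)
  expect_equal(allele_benefit_score(f(1, 1)), 1)
  expect_equal(allele_benefit_score(f(4, 1)), 2)
  expect_equal(allele_benefit_score(f(c(rep(1, 8), 100), 1)), 2)
  expect_error(allele_benefit_score(f(1, 1)[1:8, ]), "positions")
})

test_that("patient benefit scores combine classes and burden as defined", {
  bs <- patient_benefit_scores(c(A = 2), c(B = 8), tmb = 10)
  expect_equal(bs$mhc_i, 2)
  expect_equal(bs$mhc_ii, 8)
  expect_equal(bs$dual, 4)

  ones <- patient_benefit_scores(c(A = 1, B = 1), c(C = 1), tmb = 99)
  expect_equal(ones$dual, 1)
  expect_equal(ones$combined, 2)

  two <- patient_benefit_scores(c(A = 1, B = 4), c(C = 1), tmb = 0)
  expect_equal(two$mhc_i, 2)

  # permutation invariance and the geometric-mean fixed point
  base <- patient_benefit_scores(c(A = 1, B = 4), c(C = 3), 5)
  perm <- patient_benefit_scores(c(B = 4, A = 1), c(C = 3), 5)
  expect_equal(base$dual, perm$dual)
  plus <- patient_benefit_scores(c(A = 1, B = 4, D = 2), c(C = 3), 5)
  expect_equal(plus$mhc_i, base$mhc_i)

  expect_error(patient_benefit_scores(c(A = 0), c(B = 1), 1), "positive")
})

test_that("per-allele scaling factors are computed for all 9 positions", {
  world <- ts_world()
  model <- ts_model()
  sf <- allele_scaling_factors(model, world$motifs[[1]])
  expect_equal(nrow(sf), 9L)
  expect_true(all(sf$S_x >= 0 & sf$S_y >= 0))
  score <- allele_benefit_score(sf)
  expect_true(is.finite(score) && score >= 0)
})
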