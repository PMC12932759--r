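# PHBR, robustness, agretopicity, expression quartiles, allele aggregation
# and the integrated logistic model.

test_that("PHBR is the harmonic mean of per-allele best ranks", {
  expect_equal(phbr(rep(1, 6)), 1)
  expect_equal(phbr(c(0.5, 2)), 0.8)
  expect_equal(phbr(c(0.1, 1, 1, 1, 1, 1)), 0.4)
  expect_error(phbr(numeric(0)), "no allele")
  # harmonic-mean bounds: min <= PHBR <= n * min
  set.seed(3)
  for (i in 1:20) {
    r <- stats::runif(sample(2:6, 1), 0.05, 20)
    v <- phbr(r)
    expect_gte(v, min(r))
    expect_lte(v, min(r) * length(r))
  }
})

test_that("robustness counts binding alleles at the class threshold", {
  expect_equal(robustness(c(1.5, 2.0, 3.0), 2), 2)
  expect_equal(robustness(c(5, 9), 2), 0)
  expect_equal(robustness(c(5, 9, 80), Inf), 3)
})

test_that("agretopicity is the mutant/wild-type score ratio with guards", {
  expect_equal(agretopicity(0.4, 0.4), 1)
  expect_equal(agretopicity(0.8, 0.4), 2)
  expect_warning(r <- agretopicity(0.5, 0), "near zero")
  expect_equal(r, 0.5 / 1e-9)
  expect_warning(z <- agretopicity(0, 0), "zero")
  expect_equal(z, 1)
})

test_that("expression quartiles bin the per-patient TPM distribution", {
  tpm <- stats::setNames(c(1, 2, 3, 4, 5, 6, 7, 8), paste0("g", 1:8))
  q <- expression_quartile(tpm)
  expect_equal(as.vector(table(q)), rep(2L, 4))
  expect_equal(unname(q["g8"]), 4L)  # the maximum is always quartile 4
  # all-tied values share the top quartile (right-closed ECDF)
  expect_equal(unname(expression_quartile(c(a = 5, b = 5, c = 5, d = 5))),
               rep(4L, 4))
  # invariance under monotone transforms
  expect_equal(expression_quartile(log1p(tpm)), q)
  expect_warning(expression_quartile(c(a = 1, b = 2)), "fewer than 4")
})

test_that("allele aggregation handles masking, ties and empty survivor sets", {
  s <- c(A = 0.9, B = 0.4)
  r <- c(A = 5, B = 1)
  masked_max <- aggregate_alleles(s, r, "maximum", masked = TRUE,
                                  threshold = 2)
  expect_equal(masked_max$score, 0.4)  # A is masked out at rank 5 > 2
  expect_true(masked_max$presented)
  plain_max <- aggregate_alleles(s, r, "maximum", masked = FALSE,
                                 threshold = 2)
  expect_equal(plain_max$score, 0.9)
  none <- aggregate_alleles(s, c(A = 5, B = 6), "maximum", masked = TRUE,
                            threshold = 2)
  expect_equal(none$score, 0)
  expect_false(none$presented)

  # a single passing allele returns its own score under every method
  for (m in c("mean", "harmonic_mean", "weighted_average", "best_binding",
              "maximum")) {
    one <- aggregate_alleles(c(X = 0.7), c(X = 1), m, masked = TRUE,
                             threshold = 2, weight_per_allele = c(X = 2))
    expect_equal(one$score, 0.7, tolerance = 1e-6)
  }

  # masked and unmasked coincide when every allele passes
  s3 <- c(A = 0.2, B = 0.5, C = 0.8)
  r3 <- c(A = 0.5, B = 1, C = 1.5)
  for (m in c("mean", "best_binding", "maximum")) {
    expect_equal(aggregate_alleles(s3, r3, m, masked = TRUE, threshold = 2),
                 aggregate_alleles(s3, r3, m, masked = FALSE, threshold = 2))
  }

  # best-binding tie on rank resolves by allele name
  tie <- aggregate_alleles(c(B = 0.3, A = 0.6), c(B = 1, A = 1),
                           "best_binding", masked = FALSE)
  expect_equal(tie$score, 0.6)
})

test_that("the integrated model standardizes, selects and round-trips", {
  d <- make_feature_table(300, seed = 21)
  fit <- fit_integrated(d$X, d$y, retain = 5, seed = 2)
  expect_length(fit$selected_features, 5L)
  # informative features survive elimination
  expect_true(all(paste0("inf", 1:3) %in% fit$selected_features))
  # standardization constants come from the training table
  z <- scale(as.matrix(d$X[, fit$selected_features]))
  expect_equal(unname(colMeans(z)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(fit$means),
               unname(colMeans(d$X[, fit$selected_features])))
  # prediction on training data reproduces the stored logits
  pr <- predict(fit, d$X)
  beta <- fit$coefficients
  eta <- beta[["(Intercept)"]] +
    as.vector(scale(as.matrix(d$X[, fit$selected_features]),
                    fit$means, fit$sds) %*% beta[fit$selected_features])
  expect_equal(pr, 1 / (1 + exp(-eta)), tolerance = 1e-12)
})

test_that("integrated predictions follow the logistic closed form", {
  d <- make_feature_table(200, seed = 22)
  fit <- fit_integrated(d$X, d$y, retain = 5, seed = 2)
  # zero coefficients: probability 1/2 everywhere
  flat <- fit
  flat$coefficients[] <- 0
  expect_equal(unique(predict(flat, d$X)), 0.5)
  # monotone in a positive-coefficient feature
  f1 <- fit$selected_features[1]
  b1 <- fit$coefficients[[f1]]
  row <- d$X[1, , drop = FALSE]
  lo <- row; lo[[f1]] <- -1
  hi <- row; hi[[f1]] <- 1
  if (b1 > 0) expect_gt(predict(fit, hi), predict(fit, lo))
  else expect_lt(predict(fit, hi), predict(fit, lo))
  # hand-computed one-row logit
  z1 <- (unlist(row[fit$selected_features]) - fit$means) / fit$sds
  eta1 <- fit$coefficients[["(Intercept)"]] +
    sum(fit$coefficients[fit$selected_features] * z1)
  expect_equal(unname(predict(fit, row)), unname(1 / (1 + exp(-eta1))),
               tolerance = 1e-12)
  expect_error(predict(fit, d$X[, 1:2]), "missing selected feature")
})

test_that("constant features are dropped with a warning before fitting", {
  d <- make_feature_table(150, seed = 23)
  d$X$flat <- 1
  expect_warning(fit <- fit_integrated(d$X, d$y, retain = 5, seed = 2),
                 "constant")
  expect_false("flat" %in% fit$selected_features)
})
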