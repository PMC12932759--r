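# Patient-level landscape scores, burdens, CSiN/ioTNL benchmarks, Gini
# heterogeneity and the quadrant classification.

mini_profile <- function(np_i, np_ii, ccf = NULL, phbr_i = NULL,
                         cluster_id = NULL, clusters = NULL) {
  n <- length(np_i)
  m <- data.frame(mutation_id = sprintf("m%d", seq_len(n)),
                  np_immuno_i = np_i, np_immuno_ii = np_ii)
  m$ccf <- if (is.null(ccf)) rep(1, n) else ccf
  m$phbr_i <- if (is.null(phbr_i)) rep(1, n) else phbr_i
  if (!is.null(cluster_id)) m$cluster_id <- cluster_id
  suppressWarnings(tumor_profile("PT", "A1", "B1", m, clusters))
}

test_that("mutation burdens apply the published thresholds", {
  pr <- mini_profile(np_i = c(0.5, 0.3, 0.4), np_ii = c(0.5, 0.4, 0.4),
                     phbr_i = c(1.5, 2.0, 3.0))
  b <- mutation_burdens(pr)
  expect_equal(b[["tmb"]], 3)
  expect_equal(b[["tnb"]], 2)          # PHBR <= 2, boundary inclusive
  expect_equal(b[["npb"]], 2)          # duals 0.25, 0.12, 0.16: two pass
  empty <- mini_profile(numeric(0), numeric(0))
  expect_equal(unname(mutation_burdens(empty)), c(0, 0, 0))
})

test_that("dual integration supports product, sum and max", {
  expect_equal(dual_score(0.5, 0.4, "product"), 0.2)
  expect_equal(dual_score(0.7, 0, "product"), 0)
  expect_equal(dual_score(0.5, 0.4, "max"), 0.5)
  expect_equal(dual_score(0.5, 0.4, "sum"), 0.9)
})

test_that("landscape sum is the log-transformed dual-score total", {
  pr <- mini_profile(np_i = c(0.5, 0.2, 0.3), np_ii = c(1, 1, 1))
  expect_equal(landscape_sum(pr), log10(2))
  expect_equal(landscape_sum(mini_profile(numeric(0), numeric(0))), 0)
  pr0 <- mini_profile(np_i = c(0.5, 0.2, 0.3, 0.9), np_ii = c(1, 1, 1, 0))
  expect_equal(landscape_sum(pr0), log10(2))  # dual-zero mutation inert
})

test_that("CCF weighting lowers (never raises) the landscape score", {
  pr <- mini_profile(np_i = c(0.5, 0.2), np_ii = c(1, 1), ccf = c(1, 0.4))
  expect_equal(landscape_ccf(pr), log10(1.58))
  pr1 <- mini_profile(np_i = c(0.5, 0.2), np_ii = c(1, 1), ccf = c(1, 1))
  expect_equal(landscape_ccf(pr1), landscape_sum(pr1))
  pr_zero <- mini_profile(np_i = c(0.5, 0.2), np_ii = c(1, 1), ccf = c(0, 0))
  expect_equal(landscape_ccf(pr_zero), 0)
  set.seed(8)
  for (i in 1:10) {
    n <- sample(3:20, 1)
    pr_r <- mini_profile(stats::runif(n), stats::runif(n),
                         ccf = stats::runif(n))
    expect_lte(landscape_ccf(pr_r), landscape_sum(pr_r))
  }
})

test_that("clone-structured landscape weights cluster sums by prevalence", {
  # two clusters with per-cluster integrated scores 3 and 1
  cl <- data.frame(cluster_id = c("C1", "C2"), prevalence = c(1.0, 0.5))
  pr <- mini_profile(np_i = c(3, 1), np_ii = c(1, 1),
                     cluster_id = c("C1", "C2"), clusters = cl)
  expect_equal(landscape_clone(pr), log10(1 + 3.5 / 1.5))

  single <- mini_profile(np_i = c(1.5, 0.5), np_ii = c(0.25, 0.25),
                         cluster_id = c("C1", "C1"),
                         clusters = data.frame(cluster_id = "C1",
                                               prevalence = 1))
  expect_equal(landscape_clone(single), log10(1 + 2 * 0.5))

  # a zero-prevalence cluster contributes nothing to the numerator
  cl0 <- data.frame(cluster_id = c("C1", "C2"), prevalence = c(1, 0))
  pr0 <- mini_profile(np_i = c(2, 100), np_ii = c(1, 100),
                      cluster_id = c("C1", "C2"), clusters = cl0)
  expect_equal(landscape_clone(pr0), log10(1 + 2))

  all0 <- mini_profile(np_i = 1, np_ii = 1, cluster_id = "C1",
                       clusters = data.frame(cluster_id = "C1",
                                             prevalence = 0))
  expect_warning(v <- landscape_clone(all0), "prevalence")
  expect_equal(v, 0)
})

test_that("CSiN vanishes on homogeneous landscapes and filters by VAF", {
  ranks <- replicate(4, c(0.3, 1, 5), simplify = FALSE)
  expect_equal(csin(rep(0.3, 4), ranks), 0)
  # a mutation at VAF 0.04 is excluded before any cutoff
  with_low <- csin(c(0.3, 0.3, 0.3, 0.04), c(ranks[1:3], list(c(0.01, 0.1))))
  expect_equal(with_low, 0)
})

test_that("CSiN equals the literal-formula oracle on toy and random tables", {
  vaf <- c(0.4, 0.1, 0.25)
  ranks <- list(c(0.2, 0.9, 3), c(0.5, 0.6), c(1.2, 1.9, 2.5, 0.1))
  expect_equal(csin(vaf, ranks), oracle_csin(vaf, ranks), tolerance = 1e-12)
  set.seed(17)
  for (i in 1:10) {
    n <- sample(3:30, 1)
    vaf <- stats::runif(n, 0.01, 0.6)
    ranks <- lapply(seq_len(n), function(j) {
      10^stats::runif(sample(2:8, 1), -1.2, 1.3)
    })
    expect_equal(suppressWarnings(csin(vaf, ranks)),
                 suppressWarnings(oracle_csin(vaf, ranks)),
                 tolerance = 1e-9)
  }
})

test_that("ioTNL keeps clusters under the elimination cutoff", {
  cl <- data.frame(neoantigen_load = 5, n_mutations = 10, prevalence = 1)
  expect_equal(iotnl(cl), 5)                     # 5/10 = 0.5 < 1.4
  cl2 <- data.frame(neoantigen_load = 20, n_mutations = 10, prevalence = 1)
  expect_equal(iotnl(cl2), 0)                    # 2 > 1.4
  expect_equal(iotnl(rbind(cl, cl2), e = 0), 0)  # empty filter
  # monotone nondecreasing in e
  cls <- data.frame(neoantigen_load = c(5, 20, 7),
                    n_mutations = c(10, 10, 4),
                    prevalence = c(1, 0.5, 0.3))
  vals <- vapply(c(0, 0.5, 1, 1.4, 2, 5), function(e) iotnl(cls, e),
                 numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("Gini index matches hand-computed cases and scale invariance", {
  expect_equal(gini(c(1, 1, 1, 1)), 0)
  expect_equal(gini(c(0, 0, 0, 1)), 0.75)
  expect_equal(gini(c(1, 3)), 0.25)
  expect_warning(z <- gini(c(0, 0)), "zero")
  expect_equal(z, 0)
  set.seed(19)
  for (i in 1:10) {
    x <- stats::rgamma(sample(2:12, 1), 2)
    expect_equal(gini(3.7 * x), gini(x), tolerance = 1e-12)
    expect_lte(gini(x), 1 - 1 / length(x))
    expect_gte(gini(x), 0)
  }
})

test_that("heterogeneity quadrants use cohort medians with boundary rules", {
  mk <- function(id, prev, sizes) {
    cl <- data.frame(cluster_id = paste0("C", seq_along(prev)),
                     prevalence = prev, n_mutations = sizes)
    structure(list(patient_id = id, hla_i = "A", hla_ii = "B",
                   mutations = data.frame(), clusters = cl),
              class = "tumor_profile")
  }
  cohort <- list(mk("P1", c(1, 0.1), c(10, 1)),     # unequal: high gini
                 mk("P2", c(1, 0.9), c(5, 5)),      # equal: low gini
                 mk("P3", c(1), c(7)))              # single cluster: gini 0
  het <- heterogeneity_class(cohort)
  expect_equal(het$heterogeneity_class[het$patient_id == "P3"],
               "heterogeneous")  # zero gini is always <= the medians
  expect_equal(het$p_gini[3], 0)
  # a patient exactly at both medians is heterogeneous (<= rule)
  at_median <- het[het$p_gini == stats::median(het$p_gini) &
                     het$s_gini == stats::median(het$s_gini), ]
  if (nrow(at_median) > 0) {
    expect_true(all(at_median$heterogeneity_class == "heterogeneous"))
  }
  # identical patients receive identical labels
  twins <- list(mk("T1", c(1, 0.4), c(4, 2)), mk("T2", c(1, 0.4), c(4, 2)))
  het2 <- heterogeneity_class(twins)
  expect_equal(het2$heterogeneity_class[1], het2$heterogeneity_class[2])
  expect_error(heterogeneity_class(cohort[1]), "2 patients")
})

test_that("clonality summaries report clipped fractions", {
  pr <- mini_profile(np_i = c(1, 1), np_ii = c(1, 1), ccf = c(0.9, 0.5),
                     phbr_i = c(1, 1))
  cs <- clonality_summaries(pr)
  expect_equal(cs[["pct_clonal"]], 0.5)
  expect_equal(cs[["pct_binding_i"]], 1)
  all_clonal <- mini_profile(1, 1, ccf = 0.99)
  expect_equal(clonality_summaries(all_clonal)[["pct_clonal"]], 1)
  expect_warning(clonality_summaries(mini_profile(numeric(0), numeric(0))),
                 "empty")
})

test_that("landscape scores are permutation-invariant in mutation order", {
  set.seed(23)
  n <- 12
  perm <- sample(n)
  cl <- data.frame(cluster_id = c("C1", "C2", "C3"),
                   prevalence = c(1, 0.6, 0.2))
  mk <- function(ord) {
    mini_profile(stats::runif(n)[ord], stats::runif(n)[ord],
                 ccf = stats::runif(n)[ord],
                 cluster_id = sample(cl$cluster_id, n, TRUE)[ord],
                 clusters = cl)
  }
  set.seed(23); a <- mk(seq_len(n))
  set.seed(23); b <- mk(perm)
  expect_equal(landscape_sum(a), landscape_sum(b))
  expect_equal(landscape_ccf(a), landscape_ccf(b))
  expect_equal(landscape_clone(a), landscape_clone(b))
})
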