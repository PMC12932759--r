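# Triplet curation: grouping, cross-reactive pair enumeration, negative
# sampling under the BLOSUM62 sign constraint, and labelled-epitope
# curation with stratified splits.

rec <- function(cdr3, pep, allele = "ANY", cls = "I") {
  data.frame(cdr3_beta = cdr3, peptide = pep, allele = allele,
             mhc_class = cls, stringsAsFactors = FALSE)
}

test_that("complexes are grouped by (allele, CDR3) and singletons dropped", {
  pred <- accept_all_predictor("ANY")
  records <- rbind(
    rec("CASSA", "AAAAAAAAA"), rec("CASSA", "AAAAAAAAC"),
    rec("CASSB", "KLVALGINA"))
  g <- filter_and_group_complexes(records, pred)
  expect_equal(nrow(g), 1L)
  expect_setequal(g$peptides[[1]], c("AAAAAAAAA", "AAAAAAAAC"))

  # 5 records forming groups of sizes {3, 1}: only the size-3 group survives
  records5 <- rbind(
    rec("CASSA", "AAAAAAAAA"), rec("CASSA", "AAAAAAAAC"),
    rec("CASSA", "AAAAAAAAD"), rec("CASSB", "KLVALGINA"),
    rec("CASSB", "KLVALGINA"))  # duplicate collapses, leaving a singleton
  g5 <- filter_and_group_complexes(records5, pred)
  expect_equal(nrow(g5), 1L)
  expect_length(g5$peptides[[1]], 3L)
})

test_that("groups whose peptides fail the rank filter are dropped", {
  world <- ts_world()
  a <- world$alleles_i[1]
  # uniform random peptides are overwhelmingly non-binders at rank <= 2
  weak <- random_peptidome(2, 9, seed = 303)
  out <- predict_binding(world$predictor, weak, a)
  expect_true(all(out$rank_percentile > 2))  # fixture: true non-binders
  g <- filter_and_group_complexes(
    rbind(rec("CASSX", weak[1], a), rec("CASSX", weak[2], a)),
    world$predictor)
  expect_equal(nrow(g), 0L)
})

test_that("cross-reactive pairs are the ordered within-group Hamming-1 pairs", {
  g2 <- data.frame(allele = "ANY", cdr3_beta = "C1", mhc_class = "I",
                   peptides = I(list(c("AAAAAAAAA", "AAAAAAAAC"))))
  expect_equal(nrow(extract_cross_reactive_pairs(g2)), 2L)

  g_far <- data.frame(allele = "ANY", cdr3_beta = "C2", mhc_class = "I",
                      peptides = I(list(c("AAAAAAAAA", "CCCCCCCCC"))))
  expect_equal(nrow(extract_cross_reactive_pairs(g_far)), 0L)

  # 3 peptides differing pairwise at the same position: 6 ordered pairs
  g3 <- data.frame(allele = "ANY", cdr3_beta = "C3", mhc_class = "I",
                   peptides = I(list(c("AAAAAAAAA", "AAAAAAAAC",
                                       "AAAAAAAAD"))))
  expect_equal(nrow(extract_cross_reactive_pairs(g3)), 6L)
})

test_that("negative sampling honors the BLOSUM62 sign and exclusion rules", {
  B <- blosum62()
  # anchors for the published example substitutions
  expect_lt(B["A", "W"], 0)
  expect_gte(B["A", "S"], 0)

  pair <- data.frame(seed = "AAAAAAAAA", cross_reactive = "AAAAAAAAC",
                     allele = "ANY", mhc_class = "I",
                     stringsAsFactors = FALSE)
  cross_set <- c("AAAAAAAAA", "AAAAAAAAC")
  set.seed(1)
  # exhaustive candidate set: all Hamming-1 negatives from any position
  all_cand <- neoscape:::single_substitution_variants("AAAAAAAAA",
                                                      blosum_sign = "negative")
  expect_true("AAAAAAAAW" %in% all_cand)   # A->W = -3, valid
  expect_false("AAAAAAAAS" %in% all_cand)  # A->S = +1, invalid
  expect_warning(
    tri <- sample_non_cross_reactive(pair, cross_set, n_per_pair = 1000),
    "candidates")
  expect_false(any(tri$non_cross_reactive %in% cross_set))
  expect_setequal(tri$non_cross_reactive, setdiff(all_cand, cross_set))
})

test_that("triplet generation fans out 10 per pair and passes the validator", {
  world <- ts_world()
  tab <- gen_tcr_binding_table(ts_cfg(), world, seed = 7)
  groups <- filter_and_group_complexes(tab, world$predictor)
  pairs <- extract_cross_reactive_pairs(groups)
  tri <- make_triplets(tab, world$predictor, seed = 5)
  expect_equal(nrow(tri), 10L * nrow(pairs))
  expect_true(validate_triplets(tri, groups))
  # reproducibility: identical seed, identical triplets
  tri2 <- make_triplets(tab, world$predictor, seed = 5)
  expect_identical(tri, tri2)
  tri3 <- make_triplets(tab, world$predictor, seed = 6)
  expect_false(identical(tri, tri3))
})

test_that("labelled-epitope curation filters lengths and binding, then splits", {
  pred <- accept_all_predictor("ANY")
  n <- 100
  set.seed(2)
  wt <- random_peptidome(n, 9)
  records <- data.frame(wt_peptide = wt, mt_peptide = wt, allele = "ANY",
                        mhc_class = "I", label = rep(c(0, 1), each = n / 2),
                        stringsAsFactors = FALSE)
  # one extra record with mismatched length must be removed
  bad <- data.frame(wt_peptide = "AAAAAAAAA", mt_peptide = "AAAAAAAAAA",
                    allele = "ANY", mhc_class = "I", label = 1)
  out <- curate_labeled_dataset(rbind(records, bad), pred, seed = 3)
  expect_equal(nrow(out), n)
  sizes <- table(out$split)
  expect_lte(abs(sizes[["train"]] - 75), 1)
  expect_lte(abs(sizes[["val"]] - 10), 1)
  expect_lte(abs(sizes[["test"]] - 15), 1)
  # stratification: both labels appear in every split
  expect_true(all(table(out$split, out$label) > 0))
})

test_that("epitopes failing the class rank filter are removed", {
  world <- ts_world()
  a <- world$alleles_i[1]
  weak <- random_peptidome(3, 9, seed = 404)
  out <- predict_binding(world$predictor, weak, a)
  expect_true(all(out$rank_percentile > 2))  # fixture: true non-binders
  records <- data.frame(wt_peptide = weak, mt_peptide = weak, allele = a,
                        mhc_class = "I", label = c(0, 1, 1),
                        stringsAsFactors = FALSE)
  expect_equal(nrow(curate_labeled_dataset(records, world$predictor)), 0L)
})
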