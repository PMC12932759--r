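# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env()

# small synthetic world: 2 class-I + 1 class-II alleles with motifs
ts_world <- function() {
  if (is.null(.fixture_env$world)) {
    cfg <- synthetic_config(n_alleles_i = 2L, n_alleles_ii = 1L,
                            n_tcr_groups = 25L, peptidome_n = 1200L)
    .fixture_env$cfg <- cfg
    .fixture_env$world <- gen_alleles_and_motifs(cfg, seed = 42)
  }
  .fixture_env$world
}

ts_cfg <- function() {
  ts_world()
  .fixture_env$cfg
}

# uniform motif (every residue equally likely at every position)
uniform_motif <- function(allele = "UNI", mhc_class = "I") {
  m <- matrix(1 / 20, 9, 20, dimnames = list(NULL, AA_ALPHABET))
  structure(list(allele = allele, mhc_class = mhc_class, matrix = m,
                 n_source_peptides = 0L), class = "binding_motif")
}

# predictor accepting everything (rank far below any threshold), reporting
# core_start 0; handy for curation tests where binding should not filter
accept_all_predictor <- function(alleles = "ANY", mhc_class = "I") {
  classes <- stats::setNames(rep(mhc_class, length.out = length(alleles)),
                             alleles)
  structure(list(alleles = alleles, classes = classes),
            class = c("accept_all", "binding_predictor"))
}

supported_alleles.accept_all <- function(predictor) predictor$alleles

allele_class.accept_all <- function(predictor, allele) {
  unname(predictor$classes[[allele]])
}

predict_binding.accept_all <- function(predictor, peptides, allele) {
  data.frame(peptide = peptides, allele = allele,
             rank_percentile = 0.01, binding_score = 1,
             core_start = 0L, stringsAsFactors = FALSE)
}

# register the S3 methods so dispatch works inside package code
registerS3method("supported_alleles", "accept_all",
                 supported_alleles.accept_all,
                 envir = asNamespace("neoscape"))
registerS3method("allele_class", "accept_all", allele_class.accept_all,
                 envir = asNamespace("neoscape"))
registerS3method("predict_binding", "accept_all",
                 predict_binding.accept_all,
                 envir = asNamespace("neoscape"))

# a small model with deterministic random parameters
ts_model <- function(seed = 2) immuno_model(seed = seed)

# feature table with planted informative features for selection tests
make_feature_table <- function(n, seed, informative = 3, noise = 5,
                               effect = 1.0) {
  neoscape:::with_private_seed(seed, {
    X <- as.data.frame(matrix(stats::rnorm(n * (informative + noise)), n))
    names(X) <- c(paste0("inf", seq_len(informative)),
                  paste0("noise", seq_len(noise)))
    eta <- rowSums(effect * X[, seq_len(informative), drop = FALSE])
    y <- stats::rbinom(n, 1, 1 / (1 + exp(-eta)))
    list(X = X, y = y)
  })
}
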