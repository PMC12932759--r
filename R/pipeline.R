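# Pipeline driver: default run configuration consolidating every published
# threshold, per-mutation model scoring across an HLA genotype, and the
# end-to-end chain curation -> training -> scoring -> landscape.

#' Default run configuration
#'
#' All thresholds and training constants at their published defaults:
#' binding rank thresholds 2 (MHC-I) / 10 (MHC-II); PHBR presentation
#' cutoff 2; dual-score burden cutoff 0.16; clonal-CCF cutoff 0.85; ioTNL
#' elimination cutoff 1.4; triplet margin 1; 100 epochs at learning rate
#' 0.005 (AdamW); the CSiN rank cutoffs, VAF floor 0.05 and 500-mutation
#' cap; masked-maximum allele aggregation and product dual-MHC integration.
#'
#' @return A list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    rank_threshold_i = 2,
    rank_threshold_ii = 10,
    phbr_threshold = 2,
    npb_dual_threshold = 0.16,
    ccf_clonal_threshold = 0.85,
    iotnl_e = 1.4,
    csin_cutoffs = c(0.375, 0.5, 0.625, 0.75, 1.25, 1.75, 2),
    csin_vaf_min = 0.05,
    csin_mutation_cap = 500L,
    margin = 1,
    epochs = 100L,
    lr = 0.005,
    optimizer = "AdamW",
    triplet_n_per_pair = 10L,
    split_fracs = c(train = 0.75, val = 0.10, test = 0.15),
    aggregation = "maximum",
    aggregation_masked = TRUE,
    dual_integration = "product",
    seed = 1L), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("run configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = " ")))
  }
  invisible(x)
}

#' Score a tumor profile's mutations with a trained model
#'
#' For every mutation and every patient allele with a motif, runs the model
#' on the wild-type/mutant core pair with that allele's binding rank as the
#' classifier covariate, then aggregates per-allele probabilities across
#' the genotype (masked maximum by default) into `np_immuno_i` (and
#' `np_immuno_ii` when class II ranks and motifs are available).
#'
#' @param model A trained `np_immuno`.
#' @param profile A `tumor_profile` whose mutations carry `wt_core`,
#'   `mt_core` and list-columns `rank_list_i` (named per-allele class-I
#'   ranks; optionally `rank_list_ii`).
#' @param motifs Named list of `binding_motif` objects.
#' @param config A `run_config`.
#' @return The profile with `np_immuno_i` (and `np_immuno_ii`, `phbr_i`)
#'   refreshed from the model.
#' @export
score_profile <- function(model, profile, motifs,
                          config = default_run_config()) {
  p <- prep_params(model)
  m <- profile$mutations
  score_class <- function(alleles, rank_col, threshold) {
    alleles <- intersect(alleles, names(motifs))
    if (length(alleles) == 0L) return(NULL)
    cache <- build_motif_cache(p, motifs[alleles])
    vapply(seq_len(nrow(m)), function(i) {
      ranks <- m[[rank_col]][[i]]
      wt_idx <- peptide_to_indices(m$wt_core[i])
      mt_idx <- peptide_to_indices(m$mt_core[i])
      probs <- vapply(alleles, function(a) {
        bcov <- binding_covariate(ranks[[a]], cache[[a]]$mhc_class)
        forward_pair(p, cache[[a]], wt_idx, mt_idx, bcov)$prob
      }, numeric(1))
      aggregate_alleles(probs, unlist(ranks[alleles]),
                        method = config$aggregation,
                        masked = config$aggregation_masked,
                        threshold = threshold)$score
    }, numeric(1))
  }
  np_i <- score_class(profile$hla_i, "rank_list_i", config$rank_threshold_i)
  if (!is.null(np_i)) profile$mutations$np_immuno_i <- np_i
  if ("rank_list_ii" %in% names(m)) {
    np_ii <- score_class(profile$hla_ii, "rank_list_ii",
                         config$rank_threshold_ii)
    if (!is.null(np_ii)) profile$mutations$np_immuno_ii <- np_ii
  }
  profile$mutations$phbr_i <-
    vapply(profile$mutations$rank_list_i, phbr, numeric(1))
  profile
}

#' Run the full pipeline on in-memory inputs
#'
#' Chains the framework end to end: build motifs (if not supplied), curate
#' triplets from the binding table, train stage 1 (and stage 2 when
#' labelled epitopes are given), score every patient's mutations, and emit
#' one landscape row per patient plus a per-mutation score table and a run
#' manifest. Deterministic under a fixed `config$seed`.
#'
#' @param binding_records TCR-pMHC binding table (see [make_triplets()]).
#' @param cohort List of `tumor_profile` objects.
#' @param world Output of [gen_alleles_and_motifs()] or a list with
#'   `predictor` and `motifs`.
#' @param epitopes Optional labelled epitope table for stage-2 fine-tuning.
#' @param config A `run_config`.
#' @param epochs Training epochs override (the configured default of 100 is
#'   the published schedule; smaller values keep demonstration runs short).
#' @return List with `landscape` (per-patient data.frame),
#'   `mutation_scores` (per-mutation data.frame), `heterogeneity`, `model`
#'   and `manifest`.
#' @export
run_pipeline <- function(binding_records, cohort, world, epitopes = NULL,
                         config = default_run_config(),
                         epochs = config$epochs) {
  stopifnot(inherits(config, "run_config"))
  triplets <- make_triplets(
    binding_records, world$predictor,
    n_per_pair = config$triplet_n_per_pair, seed = config$seed,
    rank_thresholds = c(I = config$rank_threshold_i,
                        II = config$rank_threshold_ii))
  model <- immuno_model(margin = config$margin, seed = config$seed)
  model <- fit_stage1(model, triplets, world$motifs, epochs = epochs,
                      lr = config$lr, seed = config$seed)
  if (!is.null(epitopes)) {
    curated <- curate_labeled_dataset(
      epitopes, world$predictor, split_fracs = unname(config$split_fracs),
      seed = config$seed,
      rank_thresholds = c(I = config$rank_threshold_i,
                          II = config$rank_threshold_ii))
    model <- fit_stage2(model, curated, world$motifs, epochs = epochs,
                        lr = config$lr)
  }
  scored <- lapply(cohort, function(pr) {
    score_profile(model, pr, world$motifs, config)
  })
  landscape <- do.call(rbind, lapply(scored, function(pr) {
    landscape_summary(pr, integration = config$dual_integration)
  }))
  het <- heterogeneity_class(scored)
  mutation_scores <- do.call(rbind, lapply(scored, function(pr) {
    cbind(patient_id = pr$patient_id,
          pr$mutations[, c("mutation_id", "gene", "wt_core", "mt_core",
                           "ccf", "cluster_id", "phbr_i",
                           "np_immuno_i", "np_immuno_ii")])
  }))
  manifest <- list(
    package_version = as.character(utils::packageVersion("neoscape")),
    config = unclass(config),
    config_checksum = sum(utf8ToInt(jsonlite::toJSON(unclass(config),
                                                     auto_unbox = TRUE))),
    n_triplets = nrow(triplets),
    n_patients = length(cohort),
    epochs = epochs)
  list(landscape = landscape, mutation_scores = mutation_scores,
       heterogeneity = het, model = model, manifest = manifest)
}
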