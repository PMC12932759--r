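# Curation of cross-reactive peptide triplets from TCR-pMHC binding tables,
# and of labelled wild-type/mutant epitope sets with train/val/test splits.
#
# A triplet is (seed, cross-reactive, non-cross-reactive): the cross-reactive
# peptide shares a TCR group with the seed at Hamming distance 1; the
# non-cross-reactive peptide is a Hamming-1 variant outside the seed's
# cross-reactive set whose substitution has a negative BLOSUM62 score.

#' Filter TCR-pMHC binding records and group by (allele, CDR3)
#'
#' Keeps records with complete CDR3/peptide/allele annotation whose peptide
#' passes the class rank filter, deduplicates, groups peptides bound by the
#' same TCR on the same allele, and drops singleton groups.
#'
#' @param records Data.frame with columns `cdr3_beta`, `peptide`, `allele`,
#'   `mhc_class`.
#' @param predictor A binding predictor covering the alleles in `records`.
#' @param rank_thresholds Named numeric vector `c(I = 2, II = 10)`.
#' @return A data.frame with columns `allele`, `cdr3_beta`, `mhc_class`,
#'   `peptides` (list column of retained peptide sets, each of size >= 2).
#' @export
filter_and_group_complexes <- function(records, predictor,
                                       rank_thresholds = c(I = 2, II = 10)) {
  need <- c("cdr3_beta", "peptide", "allele", "mhc_class")
  stopifnot(all(need %in% names(records)))
  ok <- !is.na(records$cdr3_beta) & nzchar(records$cdr3_beta) &
    !is.na(records$peptide) & nzchar(records$peptide) &
    !is.na(records$allele) & nzchar(records$allele)
  records <- records[ok, , drop = FALSE]
  records <- records[!duplicated(records[, need]), , drop = FALSE]
  if (nrow(records) == 0L) {
    return(data.frame(allele = character(0), cdr3_beta = character(0),
                      mhc_class = character(0),
                      peptides = I(list())))
  }
  # rank filter, evaluated once per (peptide, allele)
  pa <- unique(records[, c("peptide", "allele", "mhc_class")])
  pa$pass <- FALSE
  for (a in unique(pa$allele)) {
    sel <- pa$allele == a
    thr <- rank_thresholds[[pa$mhc_class[sel][1]]]
    pred <- predict_binding(predictor, pa$peptide[sel], a)
    pa$pass[sel] <- pred$rank_percentile <= thr
  }
  key <- paste(records$peptide, records$allele)
  records <- records[pa$pass[match(key, paste(pa$peptide, pa$allele))], ,
                     drop = FALSE]
  sp <- split(records, paste(records$allele, records$cdr3_beta, sep = "\r"))
  groups <- lapply(sp, function(g) {
    peps <- unique(g$peptide)
    if (length(peps) < 2L) return(NULL)
    data.frame(allele = g$allele[1], cdr3_beta = g$cdr3_beta[1],
               mhc_class = g$mhc_class[1], peptides = I(list(peps)))
  })
  groups <- groups[!vapply(groups, is.null, logical(1))]
  if (length(groups) == 0L) {
    return(data.frame(allele = character(0), cdr3_beta = character(0),
                      mhc_class = character(0), peptides = I(list())))
  }
  out <- do.call(rbind, c(groups, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Enumerate cross-reactive peptide pairs within TCR groups
#'
#' All ordered within-group pairs at Hamming distance exactly 1,
#' deduplicated across groups on (seed, cross_reactive, allele). Pairs are
#' ordered (both directions emitted) because the downstream geometric
#' representation is asymmetric in wild-type vs mutant.
#'
#' @param groups Output of [filter_and_group_complexes()].
#' @return Data.frame with columns `seed`, `cross_reactive`, `allele`,
#'   `mhc_class`.
#' @export
extract_cross_reactive_pairs <- function(groups) {
  rows <- list()
  for (g in seq_len(nrow(groups))) {
    peps <- groups$peptides[[g]]
    lens <- nchar(peps)
    for (i in seq_along(peps)) {
      for (j in seq_along(peps)) {
        if (i == j || lens[i] != lens[j]) next
        if (hamming(peps[i], peps[j]) == 1L) {
          rows[[length(rows) + 1L]] <- data.frame(
            seed = peps[i], cross_reactive = peps[j],
            allele = groups$allele[g], mhc_class = groups$mhc_class[g],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(seed = character(0), cross_reactive = character(0),
                      allele = character(0), mhc_class = character(0)))
  }
  out <- do.call(rbind, rows)
  out[!duplicated(out[, c("seed", "cross_reactive", "allele")]), ,
      drop = FALSE]
}

# the cross-reactive set of a seed: all peptides sharing any group with it
# on the same allele
cross_reactive_set <- function(groups, seed, allele) {
  hit <- vapply(seq_len(nrow(groups)), function(g) {
    groups$allele[g] == allele && seed %in% groups$peptides[[g]]
  }, logical(1))
  unique(unlist(groups$peptides[hit]))
}

#' Sample non-cross-reactive peptides to complete triplets
#'
#' For one cross-reactive pair, draws up to `n_per_pair` single-substitution
#' variants of the seed (any position) whose substitution has a strictly
#' negative BLOSUM62 score and which do not belong to the seed's
#' cross-reactive set. Sampling is uniform over valid candidates, without
#' replacement; if fewer than `n_per_pair` candidates exist, all are emitted
#' with a warning.
#'
#' @param pair One-row data.frame from [extract_cross_reactive_pairs()].
#' @param cross_set Character vector: peptides sharing any group with the
#'   seed (the exclusion set).
#' @param n_per_pair Triplets per pair (default 10).
#' @return Data.frame of triplets with columns `seed`, `cross_reactive`,
#'   `non_cross_reactive`, `allele`, `mhc_class`; zero rows (with a warning)
#'   when no valid candidate exists.
#' @export
sample_non_cross_reactive <- function(pair, cross_set, n_per_pair = 10L) {
  cand <- single_substitution_variants(pair$seed, blosum_sign = "negative")
  cand <- setdiff(cand, cross_set)
  if (length(cand) == 0L) {
    warning("no valid non-cross-reactive candidate for seed ", pair$seed,
            "; pair skipped", call. = FALSE)
    return(pair[0, ])
  }
  if (length(cand) < n_per_pair) {
    warning("only ", length(cand), " candidates for seed ", pair$seed,
            " (requested ", n_per_pair, ")", call. = FALSE)
  }
  take <- sample(cand, min(n_per_pair, length(cand)))
  data.frame(seed = pair$seed, cross_reactive = pair$cross_reactive,
             non_cross_reactive = take, allele = pair$allele,
             mhc_class = pair$mhc_class, stringsAsFactors = FALSE)
}

#' Build the full cross-reactive triplet dataset
#'
#' Chains grouping, pair enumeration and negative sampling. With no
#' candidate exhaustion the output has exactly `n_per_pair` triplets per
#' cross-reactive pair.
#'
#' @inheritParams filter_and_group_complexes
#' @param n_per_pair Negatives per pair (default 10).
#' @param seed RNG seed for negative sampling.
#' @return Data.frame of triplets (see [sample_non_cross_reactive()]).
#' @export
make_triplets <- function(records, predictor, n_per_pair = 10L, seed = 1L,
                          rank_thresholds = c(I = 2, II = 10)) {
  groups <- filter_and_group_complexes(records, predictor, rank_thresholds)
  pairs <- extract_cross_reactive_pairs(groups)
  if (nrow(pairs) == 0L) {
    return(data.frame(seed = character(0), cross_reactive = character(0),
                      non_cross_reactive = character(0),
                      allele = character(0), mhc_class = character(0)))
  }
  with_private_seed(seed, {
    out <- lapply(seq_len(nrow(pairs)), function(i) {
      cs <- cross_reactive_set(groups, pairs$seed[i], pairs$allele[i])
      sample_non_cross_reactive(pairs[i, , drop = FALSE], cs, n_per_pair)
    })
    res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    rownames(res) <- NULL
    res
  })
}

#' Validate a triplet table
#'
#' Independent re-check of the triplet invariants: both the cross-reactive
#' and the non-cross-reactive peptide sit at Hamming distance 1 from the
#' seed, the non-cross-reactive substitution has a negative BLOSUM62 score,
#' and (when `groups` is given) the negative lies outside the seed's
#' cross-reactive set.
#'
#' @param triplets Data.frame from [make_triplets()].
#' @param groups Optional output of [filter_and_group_complexes()].
#' @return Invisibly TRUE; errors on the first violation.
#' @export
validate_triplets <- function(triplets, groups = NULL) {
  B <- blosum62()
  for (i in seq_len(nrow(triplets))) {
    s <- triplets$seed[i]
    if (hamming(s, triplets$cross_reactive[i]) != 1L) {
      stop("cross-reactive peptide not at Hamming distance 1 (row ", i, ")",
           call. = FALSE)
    }
    n <- triplets$non_cross_reactive[i]
    if (hamming(s, n) != 1L) {
      stop("non-cross-reactive peptide not at Hamming distance 1 (row ", i,
           ")", call. = FALSE)
    }
    p <- which(strsplit(s, "")[[1]] != strsplit(n, "")[[1]])
    if (B[substr(s, p, p), substr(n, p, p)] >= 0) {
      stop("non-cross-reactive substitution has non-negative BLOSUM62 score",
           " (row ", i, ")", call. = FALSE)
    }
    if (!is.null(groups)) {
      cs <- cross_reactive_set(groups, s, triplets$allele[i])
      if (n %in% cs) {
        stop("non-cross-reactive peptide belongs to the cross-reactive set",
             " (row ", i, ")", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Curate a labelled wild-type/mutant epitope dataset
#'
#' Removes records with mismatched wild-type/mutant peptide lengths or
#' failing the class rank filter (on the mutant peptide), then assigns
#' train/validation/test splits stratified by label.
#'
#' @param records Data.frame with columns `wt_peptide`, `mt_peptide`,
#'   `allele`, `mhc_class`, `label` (0/1).
#' @param predictor A binding predictor.
#' @param split_fracs Train/validation/test fractions (sum to 1).
#' @param seed RNG seed for the stratified split.
#' @param rank_thresholds Named numeric vector `c(I = 2, II = 10)`.
#' @return The retained records with an added `split` column taking values
#'   `"train"`, `"val"`, `"test"`.
#' @export
curate_labeled_dataset <- function(records, predictor,
                                   split_fracs = c(0.75, 0.10, 0.15),
                                   seed = 1L,
                                   rank_thresholds = c(I = 2, II = 10)) {
  stopifnot(abs(sum(split_fracs) - 1) < 1e-9)
  if (nrow(records) == 0L) {
    records$split <- character(0)
    return(records)
  }
  keep <- nchar(records$wt_peptide) == nchar(records$mt_peptide)
  records <- records[keep, , drop = FALSE]
  pass <- logical(nrow(records))
  for (a in unique(records$allele)) {
    sel <- records$allele == a
    thr <- rank_thresholds[[records$mhc_class[sel][1]]]
    pred <- predict_binding(predictor, records$mt_peptide[sel], a)
    pass[sel] <- pred$rank_percentile <= thr
  }
  records <- records[pass, , drop = FALSE]
  if (nrow(records) == 0L) {
    records$split <- character(0)
    rownames(records) <- NULL
    return(records)
  }
  records$split <- NA_character_
  with_private_seed(seed, {
    for (lab in unique(records$label)) {
      idx <- which(records$label == lab)
      n <- length(idx)
      n_train <- round(split_fracs[1] * n)
      n_val <- round(split_fracs[2] * n)
      shuffled <- sample(idx)
      records$split[shuffled[seq_len(n_train)]] <- "train"
      if (n_val > 0) {
        records$split[shuffled[n_train + seq_len(n_val)]] <- "val"
      }
      rest <- shuffled[-seq_len(n_train + n_val)]
      records$split[rest] <- "test"
    }
  })
  rownames(records) <- NULL
  records
}
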