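# Mutation-centric metrics: presentation (PHBR, robustness), differential
# binding (agretopicity), abundance (expression quartiles) and aggregation
# of allele-specific recognition scores across an HLA genotype.

#' Patient harmonic-mean best rank (PHBR)
#'
#' Harmonic mean over a patient's MHC alleles of each allele's best
#' (smallest) binding rank percentile for the mutation. Homozygous alleles
#' are counted once per genotype copy, so the vector should have one entry
#' per genotype slot (6 for MHC-I).
#'
#' @param best_rank_per_allele Numeric vector of per-allele best ranks
#'   (> 0), one entry per genotype copy.
#' @return PHBR (between the minimum and n times the minimum rank).
#' @export
phbr <- function(best_rank_per_allele) {
  r <- best_rank_per_allele
  if (length(r) == 0L) stop("no allele ranks supplied", call. = FALSE)
  stopifnot(all(r > 0))
  length(r) / sum(1 / r)
}

#' Robustness: number of binding alleles
#'
#' @param best_rank_per_allele Numeric vector of per-allele best ranks.
#' @param threshold Binder threshold (2 for MHC-I, 10 for MHC-II).
#' @return Integer count of alleles with rank <= threshold.
#' @export
robustness <- function(best_rank_per_allele, threshold) {
  stopifnot(all(best_rank_per_allele > 0))
  sum(best_rank_per_allele <= threshold)
}

#' Agretopicity ratio
#'
#' Ratio of mutant to wild-type MHC binding scores (higher = the mutant
#' binds relatively better than its wild-type counterpart). A vanishing
#' wild-type score is floored at `eps` with a warning; two zero scores
#' return 1.
#'
#' @param mt_score,wt_score Nonnegative binding scores (higher = stronger).
#' @param eps Floor for the denominator.
#' @return The ratio `mt_score / max(wt_score, eps)`.
#' @export
agretopicity <- function(mt_score, wt_score, eps = 1e-9) {
  stopifnot(mt_score >= 0, wt_score >= 0)
  if (mt_score == 0 && wt_score == 0) {
    warning("both binding scores are zero; agretopicity set to 1",
            call. = FALSE)
    return(1)
  }
  if (wt_score < eps) {
    warning("wild-type binding score near zero; ratio capped at mt/eps",
            call. = FALSE)
  }
  mt_score / max(wt_score, eps)
}

#' Per-patient expression quartiles
#'
#' Empirical-CDF quartile bins of TPM values within one patient
#' (right-closed boundaries, so ties at the maximum all land in quartile 4).
#' Invariant under any monotone transform of TPM.
#'
#' @param tpm_by_gene Named numeric vector of per-gene TPM for one patient.
#' @return Named integer vector of quartiles in 1..4.
#' @export
expression_quartile <- function(tpm_by_gene) {
  x <- tpm_by_gene
  stopifnot(length(x) >= 1L, all(is.finite(x)))
  if (length(x) < 4L) {
    warning("fewer than 4 genes; quartiles assigned from available ranks",
            call. = FALSE)
  }
  ecdf_val <- rank(x, ties.method = "max") / length(x)
  q <- as.integer(pmin(ceiling(ecdf_val * 4), 4L))
  q[q < 1L] <- 1L
  stats::setNames(q, names(x))
}

#' Aggregate allele-specific recognition scores for one mutation
#'
#' Reduces per-allele recognition scores to one mutation-centric score.
#' With `masked = TRUE` only binding alleles (rank <= threshold)
#' participate; an empty survivor set yields score 0 and
#' `presented = FALSE` (an unpresented mutation cannot be recognized).
#' Methods: `mean`, `harmonic_mean`, `weighted_average` (weights = binding
#' score), `best_binding` (score of the minimum-rank allele, ties broken by
#' allele name), `maximum`. The default mutation-centric choice in this
#' package is the masked maximum.
#'
#' @param score_per_allele Named numeric vector of recognition scores.
#' @param rank_per_allele Named numeric vector of binding rank percentiles
#'   (same names).
#' @param method One of `"mean"`, `"harmonic_mean"`, `"weighted_average"`,
#'   `"best_binding"`, `"maximum"`.
#' @param masked Restrict to binding alleles before aggregating?
#' @param threshold Binder threshold used for masking (and for `presented`).
#' @param weight_per_allele Optional weights for `weighted_average`
#'   (defaults to binding scores = `score_per_allele` is NOT used; pass the
#'   binding scores explicitly).
#' @param eps Stabilizer in the harmonic mean.
#' @return List with `score` and `presented` (any allele passing the
#'   threshold).
#' @export
aggregate_alleles <- function(score_per_allele, rank_per_allele,
                              method = c("maximum", "mean", "harmonic_mean",
                                         "weighted_average", "best_binding"),
                              masked = TRUE, threshold = 2,
                              weight_per_allele = NULL, eps = 1e-9) {
  method <- match.arg(method)
  stopifnot(length(score_per_allele) == length(rank_per_allele),
            setequal(names(score_per_allele), names(rank_per_allele)))
  rank_per_allele <- rank_per_allele[names(score_per_allele)]
  presented <- any(rank_per_allele <= threshold)
  keep <- if (masked) rank_per_allele <= threshold else {
    rep(TRUE, length(score_per_allele))
  }
  if (!any(keep)) return(list(score = 0, presented = FALSE))
  s <- score_per_allele[keep]
  r <- rank_per_allele[keep]
  w <- if (is.null(weight_per_allele)) NULL else {
    weight_per_allele[names(score_per_allele)][keep]
  }
  score <- switch(method,
    mean = mean(s),
    harmonic_mean = length(s) / sum(1 / (s + eps)),
    weighted_average = {
      if (is.null(w)) stop("weighted_average needs weight_per_allele",
                           call. = FALSE)
      sum(w * s) / sum(w)
    },
    best_binding = {
      best <- names(s)[order(r, names(s))][1]
      unname(s[best])
    },
    maximum = max(s))
  list(score = unname(score), presented = presented)
}
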