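# Pluggable MHC binding-predictor contract, with a deterministic PWM mock
# used throughout the tests and the synthetic-data generators, plus an
# adapter over externally produced tabular predictions.

CORE_LENGTH <- 9L

# run expr with a private RNG stream, restoring the caller's .Random.seed
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Predict MHC binding for peptides on one allele
#'
#' Generic contract every binding predictor implements. Implementations must
#' be deterministic for fixed inputs and either return a prediction per
#' peptide or fail with an "unsupported allele" error.
#'
#' @param predictor A predictor object (see [pwm_predictor()],
#'   [table_predictor()]).
#' @param peptides Character vector of peptides (length >= 9).
#' @param allele Allele name.
#' @return A data.frame with one row per peptide and columns `peptide`,
#'   `allele`, `rank_percentile` (> 0, lower = stronger binding),
#'   `binding_score` (higher = stronger) and `core_start` (0-based offset of
#'   the 9-mer binding core within the peptide).
#' @export
predict_binding <- function(predictor, peptides, allele) {
  UseMethod("predict_binding")
}

#' Alleles supported by a predictor
#' @param predictor A predictor object.
#' @return Character vector of allele names.
#' @export
supported_alleles <- function(predictor) UseMethod("supported_alleles")

#' MHC class of an allele under a predictor
#' @param predictor A predictor object.
#' @param allele Allele name.
#' @return `"I"` or `"II"`.
#' @export
allele_class <- function(predictor, allele) UseMethod("allele_class")

#' Default binding rank-percentile threshold for an MHC class
#'
#' Binders are called at rank <= 2 for class I and rank <= 10 for class II.
#'
#' @param mhc_class `"I"` or `"II"`.
#' @return Numeric threshold.
#' @export
rank_threshold <- function(mhc_class) {
  switch(match.arg(mhc_class, c("I", "II")), I = 2, II = 10)
}

check_allele <- function(predictor, allele) {
  if (!allele %in% supported_alleles(predictor)) {
    stop("unsupported allele: ", allele, call. = FALSE)
  }
}

#' Deterministic position-weight-matrix mock predictor
#'
#' Scores a peptide as the summed log-weights of its best 9-mer window under
#' a per-allele position weight matrix (PWM), and converts scores to rank
#' percentiles by calibration against a fixed random background sample of
#' peptides of the class-typical length (9-mers for class I, 15-mers for
#' class II). Rank percentiles are a strictly decreasing function of the
#' binding score, lie in (0, 100], and are reproducible: the calibration uses
#' a private RNG stream so construction does not disturb the caller's seed.
#'
#' @param pwms Named list of 9x20 nonnegative weight matrices (columns in
#'   [AA_ALPHABET] order), one per allele.
#' @param mhc_class `"I"` or `"II"`, recycled across alleles, or a named
#'   character vector per allele.
#' @param n_background Number of background peptides per class used for rank
#'   calibration.
#' @param calibration_seed Seed of the private calibration stream.
#' @param pseudo Small value added to PWM weights before taking logs so that
#'   zero-weight residues stay finite.
#' @return An object of class `c("pwm_predictor", "binding_predictor")`.
#' @export
pwm_predictor <- function(pwms, mhc_class = "I", n_background = 2000L,
                          calibration_seed = 760L, pseudo = 1e-6) {
  stopifnot(is.list(pwms), length(pwms) > 0, !is.null(names(pwms)))
  classes <- if (length(mhc_class) == 1L) {
    stats::setNames(rep(mhc_class, length(pwms)), names(pwms))
  } else {
    stopifnot(all(names(pwms) %in% names(mhc_class)))
    mhc_class[names(pwms)]
  }
  logw <- lapply(pwms, function(w) {
    stopifnot(is.matrix(w), nrow(w) == CORE_LENGTH, ncol(w) == 20L,
              all(is.finite(w)), all(w >= 0))
    lw <- log(w + pseudo)
    colnames(lw) <- AA_ALPHABET
    lw
  })
  obj <- structure(
    list(logw = logw, classes = classes, pseudo = pseudo,
         n_background = as.integer(n_background),
         calibration_seed = as.integer(calibration_seed)),
    class = c("pwm_predictor", "binding_predictor"))
  # background score distribution per allele, sorted, for rank lookup
  obj$background <- with_private_seed(calibration_seed, {
    lapply(names(logw), function(a) {
      len <- if (classes[[a]] == "I") 9L else 15L
      bg <- random_peptidome(n_background, len)
      sort(pwm_best_windows(obj$logw[[a]], bg)$score)
    })
  })
  names(obj$background) <- names(logw)
  obj
}

# best 9-mer window scores for equal-length peptides under a 9x20
# log-weight matrix; vectorized over peptides and windows
pwm_best_windows <- function(lw, peptides) {
  idx <- peptides_to_index_matrix(peptides)
  n_win <- ncol(idx) - CORE_LENGTH + 1L
  if (n_win < 1L) stop("peptide shorter than the 9-mer core", call. = FALSE)
  n <- nrow(idx)
  best <- rep(-Inf, n)
  start <- integer(n)
  for (s in seq_len(n_win)) {
    sc <- numeric(n)
    for (i in seq_len(CORE_LENGTH)) sc <- sc + lw[i, idx[, s + i - 1L]]
    better <- sc > best
    best[better] <- sc[better]
    start[better] <- s - 1L
  }
  list(score = best, start = start)
}

pwm_best_window <- function(lw, peptide) {
  hit <- pwm_best_windows(lw, peptide)
  list(score = hit$score, start = hit$start)
}

#' @export
supported_alleles.pwm_predictor <- function(predictor) names(predictor$logw)

#' @export
allele_class.pwm_predictor <- function(predictor, allele) {
  check_allele(predictor, allele)
  unname(predictor$classes[[allele]])
}

#' @export
predict_binding.pwm_predictor <- function(predictor, peptides, allele) {
  check_allele(predictor, allele)
  validate_peptides(peptides)
  if (any(nchar(peptides) < CORE_LENGTH)) {
    stop("peptides must be at least 9 residues long", call. = FALSE)
  }
  lw <- predictor$logw[[allele]]
  bg <- predictor$background[[allele]]
  n <- length(bg)
  if (length(unique(nchar(peptides))) == 1L) {
    hits <- pwm_best_windows(lw, peptides)
    score <- hits$score
    start <- hits$start
  } else {
    hits <- lapply(peptides, function(p) pwm_best_window(lw, p))
    score <- vapply(hits, function(h) h$score, numeric(1))
    start <- vapply(hits, function(h) h$start, integer(1))
  }
  # fraction of background scoring >= score, midpoint-corrected so that
  # ranks are strictly positive and strictly decreasing in score
  ge <- n - findInterval(score, bg, left.open = TRUE)
  data.frame(
    peptide = peptides,
    allele = allele,
    rank_percentile = 100 * (ge + 0.5) / (n + 1),
    binding_score = score,
    core_start = as.integer(start),
    stringsAsFactors = FALSE)
}

#' Adapter over precomputed tabular binding predictions
#'
#' Wraps a table of externally produced predictions (one row per
#' peptide-allele pair with columns `peptide`, `allele`, `core`, `rank`,
#' `score`, the column layout of common binding-predictor tabular output)
#' as a predictor object. `core_start` is derived by locating `core` within
#' `peptide`.
#'
#' @param table A data.frame with columns `peptide`, `allele`, `core`,
#'   `rank`, `score`.
#' @param mhc_class Named character vector allele -> class, or a single
#'   class recycled over all alleles in the table.
#' @return An object of class `c("table_predictor", "binding_predictor")`.
#' @export
table_predictor <- function(table, mhc_class = "I") {
  need <- c("peptide", "allele", "core", "rank", "score")
  if (!all(need %in% names(table))) {
    stop("table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  alleles <- unique(table$allele)
  classes <- if (length(mhc_class) == 1L) {
    stats::setNames(rep(mhc_class, length(alleles)), alleles)
  } else mhc_class
  structure(list(table = table, classes = classes),
            class = c("table_predictor", "binding_predictor"))
}

#' @export
supported_alleles.table_predictor <- function(predictor) {
  unique(predictor$table$allele)
}

#' @export
allele_class.table_predictor <- function(predictor, allele) {
  check_allele(predictor, allele)
  unname(predictor$classes[[allele]])
}

#' @export
predict_binding.table_predictor <- function(predictor, peptides, allele) {
  check_allele(predictor, allele)
  tb <- predictor$table[predictor$table$allele == allele, , drop = FALSE]
  i <- match(peptides, tb$peptide)
  if (anyNA(i)) {
    stop("no stored prediction for peptide(s): ",
         paste(utils::head(peptides[is.na(i)], 3L), collapse = ", "),
         call. = FALSE)
  }
  core_start <- mapply(function(p, core) {
    at <- regexpr(core, p, fixed = TRUE)[1]
    if (at < 1L) stop("core '", core, "' not found in peptide '", p, "'",
                      call. = FALSE)
    at - 1L
  }, peptides, tb$core[i], USE.NAMES = FALSE)
  data.frame(peptide = peptides, allele = allele,
             rank_percentile = tb$rank[i], binding_score = tb$score[i],
             core_start = as.integer(core_start), stringsAsFactors = FALSE)
}

#' Extract the 9-mer binding core of a peptide
#'
#' Runs the predictor and slices the peptide at the reported core offset.
#'
#' @inheritParams predict_binding
#' @param peptide A single peptide (length >= 9).
#' @return A list with elements `core` (9-mer string) and `prediction`
#'   (one-row data.frame as returned by [predict_binding()]).
#' @export
extract_binding_core <- function(peptide, allele, predictor) {
  stopifnot(length(peptide) == 1L)
  if (nchar(peptide) < CORE_LENGTH) {
    stop("peptide shorter than the 9-mer core", call. = FALSE)
  }
  pred <- predict_binding(predictor, peptide, allele)
  core <- substr(peptide, pred$core_start + 1L, pred$core_start + CORE_LENGTH)
  list(core = core, prediction = pred)
}

#' Build a wild-type/mutant 9-mer core pair
#'
#' Predicts on the mutant peptide, takes its reported core register, and
#' slices the wild-type peptide at the same offset. Because the input
#' peptides differ by at most one substitution, the resulting cores differ
#' at Hamming distance <= 1 by construction.
#'
#' @param wt_peptide,mt_peptide Equal-length peptides differing at <= 1
#'   position.
#' @param allele Allele name.
#' @param predictor A binding predictor.
#' @return A `core_pair` object (see [core_pair()]) with the mutant-core
#'   prediction attached as attribute `"prediction"`.
#' @export
extract_core_pair <- function(wt_peptide, mt_peptide, allele, predictor) {
  if (nchar(wt_peptide) != nchar(mt_peptide)) {
    stop("wild-type and mutant peptides must have equal length", call. = FALSE)
  }
  ext <- extract_binding_core(mt_peptide, allele, predictor)
  s <- ext$prediction$core_start
  wt_core <- substr(wt_peptide, s + 1L, s + CORE_LENGTH)
  pair <- core_pair(wt_core, ext$core, allele,
                    mhc_class = allele_class(predictor, allele))
  attr(pair, "prediction") <- ext$prediction
  pair
}

#' Wild-type/mutant core peptide pair
#'
#' A pair of aligned 9-mer binding cores for one substitution on one allele.
#' The cores must be identical (a wild-type self-pair) or differ at exactly
#' one position; `mutated_position` is the 1-based differing position (NA
#' for self-pairs).
#'
#' @param wt_core,mt_core 9-mer peptide strings.
#' @param allele Allele name.
#' @param mhc_class `"I"` or `"II"`.
#' @return An object of class `core_pair`.
#' @export
core_pair <- function(wt_core, mt_core, allele, mhc_class = "I") {
  validate_peptides(c(wt_core, mt_core), lengths = CORE_LENGTH)
  d <- hamming(wt_core, mt_core)
  if (d > 1L) {
    stop("core pair differs at ", d, " positions; at most 1 allowed",
         call. = FALSE)
  }
  pos <- if (d == 0L) NA_integer_ else {
    which(strsplit(wt_core, "")[[1]] != strsplit(mt_core, "")[[1]])
  }
  structure(list(wt_core = wt_core, mt_core = mt_core,
                 mutated_position = pos, allele = allele,
                 mhc_class = match.arg(mhc_class, c("I", "II"))),
            class = "core_pair")
}

#' @export
print.core_pair <- function(x, ...) {
  cat("core pair [", x$allele, ", MHC-", x$mhc_class, "]\n",
      "  WT ", x$wt_core, "\n  MT ", x$mt_core,
      if (!is.na(x$mutated_position))
        paste0("  (position ", x$mutated_position, ")") else "  (self-pair)",
      "\n", sep = "")
  invisible(x)
}
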