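# MHC binding-motif construction: per-allele position-specific amino-acid
# frequency matrices computed from the binding cores of predicted binders.

#' Generate a random peptidome sample
#'
#' Uniform random peptides over the canonical alphabet, used as the default
#' stand-in for a sampled human peptidome when building binding motifs.
#'
#' @param n Number of peptides.
#' @param length Peptide length (9 for class I, 15 for class II).
#' @param seed Optional seed drawn from a private RNG stream; when NULL the
#'   caller's RNG is used.
#' @return Character vector of peptides.
#' @export
random_peptidome <- function(n, length = 9L, seed = NULL) {
  gen <- function() {
    idx <- matrix(sample.int(20L, n * length, replace = TRUE), n, length)
    do.call(paste0, as.data.frame(matrix(AA_ALPHABET[idx], n, length),
                                  stringsAsFactors = FALSE))
  }
  if (is.null(seed)) gen() else with_private_seed(seed, gen())
}

#' Build an MHC binding motif for one allele
#'
#' Predicts binding for a peptidome sample, retains peptides passing the
#' rank-percentile threshold, extracts their 9-mer binding cores, and
#' tabulates position-specific amino-acid frequencies. Each motif row is a
#' frequency distribution over the 20 canonical residues (no pseudocounts:
#' frequencies may be exactly zero).
#'
#' @param peptidome Character vector of peptides, all length 9 (class I) or
#'   15 (class II).
#' @param allele Allele name supported by `predictor`.
#' @param predictor A binding predictor (see [predict_binding()]).
#' @param threshold Rank-percentile threshold retaining binders; defaults to
#'   2 for class I and 10 for class II.
#' @return An object of class `binding_motif`: list with `allele`,
#'   `mhc_class`, `matrix` (9x20, rows sum to 1) and `n_source_peptides`.
#' @export
build_binding_motif <- function(peptidome, allele, predictor,
                                threshold = NULL) {
  cls <- allele_class(predictor, allele)
  expected_len <- if (cls == "I") 9L else 15L
  validate_peptides(peptidome, lengths = expected_len)
  if (is.null(threshold)) threshold <- rank_threshold(cls)
  pred <- predict_binding(predictor, peptidome, allele)
  keep <- pred$rank_percentile <= threshold
  if (!any(keep)) {
    stop("zero binders for allele ", allele, " at rank threshold ", threshold,
         "; consider relaxing the threshold", call. = FALSE)
  }
  cores <- substr(pred$peptide[keep], pred$core_start[keep] + 1L,
                  pred$core_start[keep] + CORE_LENGTH)
  motif_from_cores(cores, allele, cls)
}

#' Build a binding motif directly from 9-mer cores
#'
#' @param cores Character vector of 9-mer binding cores.
#' @param allele Allele name.
#' @param mhc_class `"I"` or `"II"`.
#' @return A `binding_motif` object.
#' @export
motif_from_cores <- function(cores, allele, mhc_class = "I") {
  validate_peptides(cores, lengths = CORE_LENGTH)
  idx <- peptides_to_index_matrix(cores)
  m <- matrix(0, nrow = CORE_LENGTH, ncol = 20L,
              dimnames = list(NULL, AA_ALPHABET))
  for (i in seq_len(CORE_LENGTH)) {
    m[i, ] <- tabulate(idx[, i], nbins = 20L) / nrow(idx)
  }
  structure(list(allele = allele,
                 mhc_class = match.arg(mhc_class, c("I", "II")),
                 matrix = m, n_source_peptides = length(cores)),
            class = "binding_motif")
}

#' @export
print.binding_motif <- function(x, ...) {
  cat("binding motif for ", x$allele, " (MHC-", x$mhc_class, "), built from ",
      x$n_source_peptides, " cores\n", sep = "")
  consensus <- AA_ALPHABET[apply(x$matrix, 1, which.max)]
  cat("  consensus:", paste(consensus, collapse = ""), "\n")
  invisible(x)
}

validate_motif <- function(motif) {
  stopifnot(inherits(motif, "binding_motif"),
            is.matrix(motif$matrix),
            nrow(motif$matrix) == CORE_LENGTH,
            ncol(motif$matrix) == 20L,
            all(motif$matrix >= 0))
  if (any(abs(rowSums(motif$matrix) - 1) > 1e-9)) {
    stop("motif rows must each sum to 1", call. = FALSE)
  }
  invisible(motif)
}

#' Write a binding motif to TSV
#'
#' Nine rows by twenty named residue columns plus a `position` column; the
#' allele name and class are stored in `#` header comments.
#'
#' @param motif A `binding_motif`.
#' @param path Output file path.
#' @export
write_motif_tsv <- function(motif, path) {
  validate_motif(motif)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#allele=", motif$allele),
               paste0("#mhc_class=", motif$mhc_class),
               paste0("#n_source_peptides=", motif$n_source_peptides)), con)
  df <- data.frame(position = seq_len(CORE_LENGTH), motif$matrix,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a binding motif from TSV
#'
#' @param path Path written by [write_motif_tsv()].
#' @return A `binding_motif` object.
#' @export
read_motif_tsv <- function(path) {
  header <- grep("^#", readLines(path, n = 10L), value = TRUE)
  field <- function(key) {
    ln <- grep(paste0("^#", key, "="), header, value = TRUE)
    if (length(ln) != 1L) stop("missing #", key, "= header in ", path,
                               call. = FALSE)
    sub(paste0("^#", key, "="), "", ln)
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE)
  m <- as.matrix(df[order(df$position), AA_ALPHABET])
  dimnames(m) <- list(NULL, AA_ALPHABET)
  out <- structure(list(allele = field("allele"),
                        mhc_class = field("mhc_class"),
                        matrix = m,
                        n_source_peptides = as.integer(field("n_source_peptides"))),
                   class = "binding_motif")
  validate_motif(out)
}
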