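# Amino-acid alphabet primitives shared by every module.

#' The 20 canonical amino acids
#'
#' Single-letter codes in the conventional BLOSUM row order. All peptide,
#' motif and embedding matrices in this package index residues in this order.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.neoscape_env <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix over the canonical alphabet
#'
#' Returns the 20x20 BLOSUM62 matrix (from \pkg{Biostrings}) restricted to
#' the canonical amino acids, rows and columns ordered as [AA_ALPHABET].
#' Ambiguity codes (B, Z, X, U, J, *) are excluded: peptides containing them
#' are rejected at ingest because the residue transform underlying the
#' embedding layer is only defined for canonical residues.
#'
#' @return Numeric 20x20 symmetric matrix.
#' @export
blosum62 <- function() {
  if (is.null(.neoscape_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
    storage.mode(m) <- "double"
    .neoscape_env$blosum62 <- m
  }
  .neoscape_env$blosum62
}

#' Validate peptide sequences
#'
#' Checks that peptides use only the 20 canonical amino acids and,
#' optionally, that they have one of the allowed lengths.
#'
#' @param peptides Character vector of peptide sequences.
#' @param lengths Optional integer vector of allowed lengths.
#' @return Invisibly, `peptides`; errors on the first violation.
#' @export
validate_peptides <- function(peptides, lengths = NULL) {
  if (!is.character(peptides) || anyNA(peptides)) {
    stop("peptides must be a character vector without NA", call. = FALSE)
  }
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), peptides)
  if (any(bad)) {
    stop("non-canonical residue in peptide(s): ",
         paste(utils::head(peptides[bad], 3L), collapse = ", "), call. = FALSE)
  }
  if (!is.null(lengths) && !all(nchar(peptides) %in% lengths)) {
    stop("peptide length must be one of ", paste(lengths, collapse = "/"),
         call. = FALSE)
  }
  invisible(peptides)
}

# residue index lookup: peptide string -> integer vector in 1..20
peptide_to_indices <- function(peptide) {
  idx <- match(strsplit(peptide, "", fixed = TRUE)[[1]], AA_ALPHABET)
  if (anyNA(idx)) stop("non-canonical residue in '", peptide, "'", call. = FALSE)
  idx
}

# matrix of residue indices for equal-length peptides (n x L)
peptides_to_index_matrix <- function(peptides) {
  L <- unique(nchar(peptides))
  if (length(L) != 1L) stop("peptides must share one length", call. = FALSE)
  idx <- match(unlist(strsplit(peptides, "", fixed = TRUE)), AA_ALPHABET)
  if (anyNA(idx)) stop("non-canonical residue in peptide(s)", call. = FALSE)
  matrix(idx, ncol = L, byrow = TRUE)
}

#' Hamming distance between two equal-length peptides
#'
#' @param a,b Peptide strings of equal length.
#' @return Integer count of differing positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("peptides must have equal length", call. = FALSE)
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# vectorised Hamming for two character vectors of equal-length strings
hamming_vec <- function(a, b) {
  mapply(hamming, a, b, USE.NAMES = FALSE)
}

# all single-substitution variants of `peptide` whose substitution has a
# BLOSUM62 score with the stated sign; returns character vector
single_substitution_variants <- function(peptide, blosum_sign = NULL) {
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  B <- blosum62()
  out <- character(0)
  for (i in seq_along(res)) {
    for (aa in AA_ALPHABET) {
      if (aa == res[i]) next
      if (!is.null(blosum_sign)) {
        sc <- B[res[i], aa]
        if (blosum_sign == "negative" && sc >= 0) next
        if (blosum_sign == "positive" && sc <= 0) next
      }
      v <- res
      v[i] <- aa
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}
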