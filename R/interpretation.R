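# Interpretation of the trained model: PCA residue embeddings from
# substitution matrices (baselines), position-wise motif-enriched residue
# embeddings, affine-transformation analysis with SVD-derived axis scaling
# factors, and allele/patient benefit scores.

#' 2-D PCA embedding of a substitution matrix
#'
#' Treats each amino acid's row of a symmetric 20x20 substitution matrix
#' (BLOSUM62, PMBEC, ...) as its feature vector and projects onto the top
#' two principal components. Sign convention: within each component the
#' loading of largest magnitude is made positive, so the embedding is
#' deterministic.
#'
#' @param substitution_matrix Symmetric numeric 20x20 matrix with rows and
#'   columns in [AA_ALPHABET] order (or named so they can be reordered).
#' @return 20x2 matrix of residue coordinates, rownames [AA_ALPHABET].
#' @export
pca_embedding <- function(substitution_matrix) {
  m <- substitution_matrix
  stopifnot(is.matrix(m), nrow(m) == 20L, ncol(m) == 20L)
  if (!is.null(rownames(m)) && all(AA_ALPHABET %in% rownames(m))) {
    m <- m[AA_ALPHABET, AA_ALPHABET]
  }
  if (max(abs(m - t(m))) > 1e-8) {
    stop("substitution matrix must be symmetric", call. = FALSE)
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  emb <- pc$x[, 1:2, drop = FALSE]
  for (j in 1:2) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) emb[, j] <- -emb[, j]
  }
  dimnames(emb) <- list(AA_ALPHABET, c("PC1", "PC2"))
  emb
}

#' Raw residue embedding of a trained model
#'
#' The 20 canonical residues mapped through the model's residue transform
#' (BLOSUM62 row followed by the learned affine map), without motif
#' enrichment.
#'
#' @param model An `np_immuno` object.
#' @return 20 x d_a matrix, rownames [AA_ALPHABET].
#' @export
residue_embedding <- function(model) {
  stopifnot(inherits(model, "np_immuno"))
  emb <- residue_embedding_table(model$params)
  rownames(emb) <- AA_ALPHABET
  emb
}

#' Motif-enriched residue embedding at one core position
#'
#' Places each of the 20 residues at the given core position of the given
#' allele and returns its motif-enriched coordinates there. Because the
#' enrichment acts position-wise, the other positions are irrelevant and the
#' map is linear in the residue embedding.
#'
#' @param model An `np_immuno` object.
#' @param motif The allele's `binding_motif`.
#' @param position Core position, 1..9.
#' @return 20 x d_p matrix of enriched coordinates, rownames [AA_ALPHABET].
#' @export
motif_enriched_residue_embedding <- function(model, motif, position) {
  stopifnot(inherits(model, "np_immuno"),
            position %in% seq_len(CORE_LENGTH))
  p <- prep_params(model)
  ce <- motif_cache_entry(p, motif)
  K <- dim(ce$C)[3]
  d_a <- ncol(p$.Emb)
  d_p <- nrow(p$W_proj)
  # enriched[r, p'] = sum_k W_proj[p', k] * sum_d C[pos, d, k] * Emb[r, d]
  Tmap <- matrix(0, d_p, d_a)
  for (k in seq_len(K)) {
    Tmap <- Tmap + outer(p$W_proj[, k], ce$C[position, , k])
  }
  out <- p$.Emb %*% t(Tmap)
  dimnames(out) <- list(AA_ALPHABET, NULL)
  out
}

#' Least-squares affine fit between two point clouds
#'
#' Fits `E_m ~ E_r A + t` (row-vector convention) by least squares over the
#' 20 matched residue points, reporting the 2x2 linear part, the translation
#' and the mean squared residual.
#'
#' @param E_r,E_m Matched 20x2 matrices (reference and transformed clouds).
#' @return List with elements `A` (2x2), `t` (length 2), `residual`.
#' @export
fit_affine <- function(E_r, E_m) {
  stopifnot(is.matrix(E_r), is.matrix(E_m), all(dim(E_r) == dim(E_m)),
            ncol(E_r) == 2L)
  X <- cbind(E_r, 1)
  if (qr(X)$rank < 3L) {
    stop("degenerate fit: reference cloud is rank-deficient", call. = FALSE)
  }
  coefs <- qr.solve(X, E_m)
  A <- coefs[1:2, , drop = FALSE]
  t_vec <- coefs[3, ]
  fitted <- X %*% coefs
  list(A = A, t = t_vec, residual = mean((E_m - fitted)^2))
}

#' Axis scaling factors of an affine map
#'
#' Singular value decomposition A = U diag(sigma) V' projected back onto the
#' original axes: `S_x = |V[1,1] sigma_1| + |V[1,2] sigma_2|` and
#' `S_y = |V[2,1] sigma_1| + |V[2,2] sigma_2|`, where V's columns are the
#' right singular vectors ordered by decreasing singular value. Absolute
#' values make the factors invariant to singular-vector sign flips.
#'
#' @param A 2x2 matrix.
#' @return Named numeric vector `c(S_x, S_y)`, both >= 0.
#' @export
scaling_factors <- function(A) {
  stopifnot(is.matrix(A), all(dim(A) == c(2L, 2L)), all(is.finite(A)))
  sv <- svd(A)
  c(S_x = sum(abs(sv$v[1, ] * sv$d)),
    S_y = sum(abs(sv$v[2, ] * sv$d)))
}

#' Per-position scaling factors for one allele
#'
#' For each of the 9 core positions, fits the affine map from the raw
#' residue embedding to the motif-enriched embedding at that position and
#' extracts the axis scaling factors.
#'
#' @param model An `np_immuno` object.
#' @param motif The allele's `binding_motif`.
#' @return Data.frame with columns `allele`, `position`, `S_x`, `S_y`,
#'   `residual`.
#' @export
allele_scaling_factors <- function(model, motif) {
  E_r <- residue_embedding(model)[, 1:2]
  out <- lapply(seq_len(CORE_LENGTH), function(pos) {
    E_m <- motif_enriched_residue_embedding(model, motif, pos)[, 1:2]
    fit <- fit_affine(E_r, E_m)
    sf <- scaling_factors(fit$A)
    data.frame(allele = motif$allele, position = pos,
               S_x = sf[["S_x"]], S_y = sf[["S_y"]],
               residual = fit$residual)
  })
  do.call(rbind, out)
}

#' Allele benefit score
#'
#' Average geometric mean of the axis scaling factors across the 9 core
#' positions: larger values mean the allele's motif stretches residue
#' distances more, i.e. wild-type/mutant pairs are pushed further apart.
#'
#' @param factors Data.frame from [allele_scaling_factors()] for exactly one
#'   allele (9 positions).
#' @return Single numeric benefit score.
#' @export
allele_benefit_score <- function(factors) {
  stopifnot(all(c("position", "S_x", "S_y") %in% names(factors)))
  if (!setequal(factors$position, seq_len(CORE_LENGTH)) ||
      nrow(factors) != CORE_LENGTH) {
    stop("factors must cover positions 1..9 exactly once", call. = FALSE)
  }
  mean(sqrt(factors$S_x * factors$S_y))
}

geometric_mean <- function(x) exp(mean(log(x)))

#' Patient-level benefit scores
#'
#' Aggregates per-allele benefit scores over a patient's HLA genotype:
#' geometric mean within each MHC class, geometric mean of the two class
#' scores (`dual`), and the combination with mutation burden
#' `combined = log10(tmb + 1) * dual`.
#'
#' @param allele_scores_i,allele_scores_ii Named numeric vectors of positive
#'   per-allele benefit scores for the patient's MHC-I and MHC-II alleles.
#' @param tmb Tumor mutation burden (count >= 0).
#' @return List with elements `per_allele`, `mhc_i`, `mhc_ii`, `dual`,
#'   `combined`.
#' @export
patient_benefit_scores <- function(allele_scores_i, allele_scores_ii, tmb) {
  stopifnot(length(allele_scores_i) >= 1L, length(allele_scores_ii) >= 1L,
            tmb >= 0)
  if (any(c(allele_scores_i, allele_scores_ii) <= 0)) {
    stop("allele benefit scores must be positive", call. = FALSE)
  }
  mhc_i <- geometric_mean(allele_scores_i)
  mhc_ii <- geometric_mean(allele_scores_ii)
  dual <- sqrt(mhc_i * mhc_ii)
  list(per_allele = c(allele_scores_i, allele_scores_ii),
       mhc_i = mhc_i, mhc_ii = mhc_ii, dual = dual,
       combined = log10(tmb + 1) * dual)
}
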