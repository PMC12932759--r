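# Forward pass and analytic gradients of the cross-reactivity-distance
# network. The backward pass mirrors the forward step by step; it is checked
# against central finite differences in the test suite.

# residue embedding table: 20 x d_a (one row per canonical residue)
residue_embedding_table <- function(params) {
  sweep(blosum62() %*% params$W_embed, 2, params$b_embed, `+`)
}

# per-allele cache: motif embedding and motif-modulated kernels
# Xm = M B62 (9 x 20), Em = Xm W_e + b (9 x d_a), C[,,k] = Em W_conv[,,k]
motif_cache_entry <- function(params, motif) {
  validate_motif(motif)
  Xm <- motif$matrix %*% blosum62()
  Em <- sweep(Xm %*% params$W_embed, 2, params$b_embed, `+`)
  K <- dim(params$W_conv)[3]
  C <- array(0, dim = c(CORE_LENGTH, ncol(Em), K))
  for (k in seq_len(K)) C[, , k] <- Em %*% params$W_conv[, , k]
  list(Xm = Xm, Em = Em, C = C, mhc_class = motif$mhc_class,
       allele = motif$allele)
}

build_motif_cache <- function(params, motifs) {
  stopifnot(is.list(motifs), !is.null(names(motifs)))
  lapply(motifs, function(m) motif_cache_entry(params, m))
}

# single-peptide branch: residue indices -> pooled peptide embedding
# returns intermediates needed by the backward pass
forward_peptide <- function(params, cache_entry, idx, w) {
  Emb <- params$.Emb  # 20 x d_a, precomputed per step
  E <- Emb[idx, , drop = FALSE]                       # 9 x d_a
  C <- cache_entry$C
  K <- dim(C)[3]
  H <- matrix(0, K, CORE_LENGTH)                      # H[k, i]
  for (k in seq_len(K)) H[k, ] <- rowSums(C[, , k] * E)
  G <- t(params$W_proj %*% H)                         # 9 x d_p (enriched)
  v <- as.vector(crossprod(G, w))                     # d_p
  list(idx = idx, E = E, H = H, G = G, v = v)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# pair forward: wild-type and mutant cores on one allele
# bcov may be NA when only distances are needed
forward_pair <- function(params, cache_entry, wt_idx, mt_idx, bcov = NA_real_) {
  w <- if (cache_entry$mhc_class == "I") params$w_pos_I else params$w_pos_II
  fw <- forward_peptide(params, cache_entry, wt_idx, w)
  fm <- forward_peptide(params, cache_entry, mt_idx, w)
  delta <- fm$v - fw$v
  dist <- sqrt(sum(delta^2))
  dir <- delta / (dist + params$.eps)
  u <- c(fw$v, dir)
  z1 <- as.vector(crossprod(params$scale_W1, u)) + params$scale_b1
  h <- tanh(z1)
  s <- sum(params$scale_W2 * h) + params$scale_b2
  sig_s <- sigmoid(s)
  crd <- dist * sig_s
  logit <- if (is.na(bcov)) NA_real_ else {
    params$W_out[1] * crd + params$W_out[2] * bcov + params$b_out
  }
  list(wt = fw, mt = fm, w = w, delta = delta, dist = dist, dir = dir,
       u = u, h = h, s = s, sig_s = sig_s, crd = crd, bcov = bcov,
       logit = logit, prob = if (is.na(bcov)) NA_real_ else sigmoid(logit),
       mhc_class = cache_entry$mhc_class)
}

# accumulate gradients of one pair into `gr` (a zero_grads() list held in an
# environment for in-place mutation). Upstream: g_crd (d loss / d CRD) and
# g_logit (d loss / d classifier logit; 0 in stage 1).
backward_pair <- function(params, cache_entry, tr, g_crd, g_logit, env) {
  gr <- env$gr
  if (g_logit != 0) {
    gr$W_out <- gr$W_out + g_logit * c(tr$crd, tr$bcov)
    gr$b_out <- gr$b_out + g_logit
    g_crd <- g_crd + g_logit * params$W_out[1]
  }
  if (g_crd == 0) {
    env$gr <- gr
    return(invisible(NULL))
  }
  # CRD = dist * sigmoid(s)
  g_dist <- g_crd * tr$sig_s
  g_s <- g_crd * tr$dist * tr$sig_s * (1 - tr$sig_s)
  # scaling network
  g_h <- g_s * params$scale_W2
  g_z1 <- g_h * (1 - tr$h^2)
  gr$scale_W2 <- gr$scale_W2 + g_s * tr$h
  gr$scale_b2 <- gr$scale_b2 + g_s
  gr$scale_W1 <- gr$scale_W1 + outer(tr$u, g_z1)
  gr$scale_b1 <- gr$scale_b1 + g_z1
  g_u <- as.vector(params$scale_W1 %*% g_z1)
  d_p <- length(tr$wt$v)
  g_vwt <- g_u[seq_len(d_p)]
  g_dir <- g_u[d_p + seq_len(d_p)]
  # direction = delta / (dist + eps), dist = ||delta||
  g_delta <- numeric(d_p)
  if (tr$dist > 0) {
    de <- tr$dist + params$.eps
    g_delta <- g_dir / de -
      tr$delta * sum(g_dir * tr$delta) / (tr$dist * de^2)
    g_delta <- g_delta + g_dist * tr$delta / tr$dist
  }
  g_vmt <- g_delta
  g_vwt <- g_vwt - g_delta
  gr <- backward_peptide(params, cache_entry, tr$wt, g_vwt, tr$mhc_class, gr)
  gr <- backward_peptide(params, cache_entry, tr$mt, g_vmt, tr$mhc_class, gr)
  env$gr <- gr
  invisible(NULL)
}

backward_peptide <- function(params, cache_entry, fp, g_v, mhc_class, gr) {
  if (all(g_v == 0)) return(gr)
  w_name <- if (mhc_class == "I") "w_pos_I" else "w_pos_II"
  w <- params[[w_name]]
  # v[p] = sum_i w_i G[i, p]
  gr[[w_name]] <- gr[[w_name]] + as.vector(fp$G %*% g_v)
  gG <- outer(w, g_v)                                  # 9 x d_p
  # G = t(W_proj H)
  gH <- crossprod(params$W_proj, t(gG))                # K x 9
  gr$W_proj <- gr$W_proj + t(gG) %*% t(fp$H)
  C <- cache_entry$C
  K <- dim(C)[3]
  gE <- fp$E * 0
  gEm <- cache_entry$Em * 0
  for (k in seq_len(K)) {
    gHk <- gH[k, ]
    gE <- gE + C[, , k] * gHk
    gCk <- fp$E * gHk
    gr$W_conv[, , k] <- gr$W_conv[, , k] + crossprod(cache_entry$Em, gCk)
    gEm <- gEm + gCk %*% t(params$W_conv[, , k])
  }
  # peptide residues index the shared embedding table
  for (i in seq_len(CORE_LENGTH)) {
    gr$.Emb[fp$idx[i], ] <- gr$.Emb[fp$idx[i], ] + gE[i, ]
  }
  # motif embedding Em = Xm W_e + b
  gr$W_embed <- gr$W_embed + crossprod(cache_entry$Xm, gEm)
  gr$b_embed <- gr$b_embed + colSums(gEm)
  gr
}

# prepare params for a training/prediction step: precompute the embedding
# table and stash epsilon where the forward pass can reach it
prep_params <- function(model) {
  p <- model$params
  p$.Emb <- residue_embedding_table(p)
  p$.eps <- model$hyper$epsilon
  p
}

# fold the embedding-table gradient back onto W_embed / b_embed
finalize_grads <- function(gr) {
  gr$W_embed <- gr$W_embed + crossprod(blosum62(), gr$.Emb)
  gr$b_embed <- gr$b_embed + colSums(gr$.Emb)
  gr$.Emb <- NULL
  gr
}

new_grad_env <- function(params) {
  gr <- zero_grads(params[!startsWith(names(params), ".")])
  gr$.Emb <- matrix(0, 20, ncol(params$W_embed))
  env <- new.env(parent = emptyenv())
  env$gr <- gr
  env
}

#' Binding covariate from a rank percentile
#'
#' Bounded binding-strength encoding `1 - min(rank, R) / R` with R the class
#' rank threshold (2 for MHC-I, 10 for MHC-II): 1 at vanishing rank, 0 at or
#' beyond the binder threshold.
#'
#' @param rank Rank percentile(s), > 0.
#' @param mhc_class `"I"` or `"II"`.
#' @return Numeric in [0, 1].
#' @export
binding_covariate <- function(rank, mhc_class = "I") {
  R <- rank_threshold(mhc_class)
  1 - pmin(rank, R) / R
}

#' Full forward trace for one core pair
#'
#' Runs the network on an aligned wild-type/mutant core pair and returns
#' every intermediate quantity: residue and motif embeddings, enriched
#' embeddings, pooled peptide vectors, the geometric representation
#' (origin, direction, distance), CRD and, when a binding rank is supplied,
#' the immunogenicity probability.
#'
#' @param model An `np_immuno` object.
#' @param pair A [core_pair()] (or list with `wt_core`, `mt_core`).
#' @param motif The [build_binding_motif()] result for the pair's allele.
#' @param binding_rank Optional rank percentile of the mutant peptide used
#'   for the classifier covariate.
#' @return A list with elements `E_wt`, `E_mt`, `E_motif`, `enriched_wt`,
#'   `enriched_mt`, `v_wt`, `v_mt`, `origin`, `direction`, `distance`,
#'   `crd`, `probability`.
#' @export
forward_trace <- function(model, pair, motif, binding_rank = NA_real_) {
  stopifnot(inherits(model, "np_immuno"))
  if (!is.null(pair$allele) && !is.null(motif$allele) &&
      pair$allele != motif$allele) {
    stop("pair and motif allele mismatch: ", pair$allele, " vs ",
         motif$allele, call. = FALSE)
  }
  p <- prep_params(model)
  ce <- motif_cache_entry(p, motif)
  bcov <- if (is.na(binding_rank)) NA_real_ else {
    binding_covariate(binding_rank, motif$mhc_class)
  }
  tr <- forward_pair(p, ce, peptide_to_indices(pair$wt_core),
                     peptide_to_indices(pair$mt_core), bcov)
  list(E_wt = tr$wt$E, E_mt = tr$mt$E, E_motif = ce$Em,
       enriched_wt = tr$wt$G, enriched_mt = tr$mt$G,
       v_wt = tr$wt$v, v_mt = tr$mt$v,
       origin = tr$wt$v, direction = tr$dir, distance = tr$dist,
       crd = tr$crd, probability = tr$prob)
}

#' Component scores for one core pair
#'
#' Extracts the incrementally constructed distances the model is built
#' from: `SubDist` (Euclidean distance of the raw residue embeddings at the
#' mutated position), `SubPosDist` (distance of the position-weight-pooled
#' raw embeddings), `GeoDist` (distance after motif enrichment; the `d` of
#' the geometric representation) and `CRD` (GeoDist after sigmoid scaling).
#' Self-pairs score 0 on all components.
#'
#' @inheritParams forward_trace
#' @return Named numeric vector with elements `SubDist`, `SubPosDist`,
#'   `GeoDist`, `CRD`.
#' @export
component_scores <- function(model, pair, motif) {
  stopifnot(inherits(model, "np_immuno"))
  p <- prep_params(model)
  wt_idx <- peptide_to_indices(pair$wt_core)
  mt_idx <- peptide_to_indices(pair$mt_core)
  w <- if (motif$mhc_class == "I") p$w_pos_I else p$w_pos_II
  diff_pos <- which(wt_idx != mt_idx)
  if (length(diff_pos) == 0L) {
    return(c(SubDist = 0, SubPosDist = 0, GeoDist = 0, CRD = 0))
  }
  Emb <- p$.Emb
  sub <- sqrt(sum((Emb[wt_idx[diff_pos], ] - Emb[mt_idx[diff_pos], ])^2))
  v_raw_wt <- as.vector(crossprod(Emb[wt_idx, , drop = FALSE], w))
  v_raw_mt <- as.vector(crossprod(Emb[mt_idx, , drop = FALSE], w))
  subpos <- sqrt(sum((v_raw_mt - v_raw_wt)^2))
  ce <- motif_cache_entry(p, motif)
  tr <- forward_pair(p, ce, wt_idx, mt_idx)
  c(SubDist = sub, SubPosDist = subpos, GeoDist = tr$dist, CRD = tr$crd)
}

#' Predict immunogenicity for a table of core pairs
#'
#' @param object An `np_immuno` model.
#' @param pairs Data.frame with columns `wt_core`, `mt_core`, `allele` and
#'   optionally `rank_percentile` (mutant binding rank, used for the
#'   classifier covariate; rows without it get `probability = NA`).
#' @param motifs Named list of `binding_motif` objects covering the alleles
#'   in `pairs`.
#' @param ... Unused.
#' @return `pairs` with added columns `SubDist`, `SubPosDist`, `GeoDist`,
#'   `CRD` and `probability`.
#' @export
predict.np_immuno <- function(object, pairs, motifs, ...) {
  stopifnot(is.data.frame(pairs),
            all(c("wt_core", "mt_core", "allele") %in% names(pairs)))
  missing_motif <- setdiff(unique(pairs$allele), names(motifs))
  if (length(missing_motif) > 0L) {
    stop("no motif for allele(s): ", paste(missing_motif, collapse = ", "),
         call. = FALSE)
  }
  p <- prep_params(object)
  cache <- build_motif_cache(p, motifs[unique(pairs$allele)])
  ranks <- if ("rank_percentile" %in% names(pairs)) {
    pairs$rank_percentile
  } else rep(NA_real_, nrow(pairs))
  out <- matrix(NA_real_, nrow(pairs), 5,
                dimnames = list(NULL, c("SubDist", "SubPosDist", "GeoDist",
                                        "CRD", "probability")))
  for (i in seq_len(nrow(pairs))) {
    ce <- cache[[pairs$allele[i]]]
    pr <- list(wt_core = pairs$wt_core[i], mt_core = pairs$mt_core[i])
    motif <- motifs[[pairs$allele[i]]]
    cs <- component_scores(object, pr, motif)
    bcov <- if (is.na(ranks[i])) NA_real_ else {
      binding_covariate(ranks[i], ce$mhc_class)
    }
    tr <- forward_pair(p, ce, peptide_to_indices(pr$wt_core),
                       peptide_to_indices(pr$mt_core), bcov)
    out[i, ] <- c(cs[["SubDist"]], cs[["SubPosDist"]], cs[["GeoDist"]],
                  tr$crd, tr$prob)
  }
  cbind(pairs, as.data.frame(out))
}
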