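# Independent, loop-based oracles. These re-derive results directly from
# the defining equations with explicit scalar loops and share no code with
# the vectorized implementation they check.

# full forward pass: one-hot -> BLOSUM62 -> affine embed -> motif-modulated
# kernels -> projection -> position-weighted pooling -> geometric
# representation -> scaled distance -> classifier
oracle_forward <- function(params, motif_matrix, wt, mt, mhc_class,
                           bcov = NA, eps = 1e-8) {
  B <- blosum62()
  L <- 9L
  d_a <- ncol(params$W_embed)
  d_p <- nrow(params$W_proj)
  K <- dim(params$W_conv)[3]
  onehot <- function(pep) {
    P <- matrix(0, L, 20)
    chars <- strsplit(pep, "")[[1]]
    for (i in 1:L) P[i, which(colnames(B) == chars[i])] <- 1
    P
  }
  embed <- function(X) {
    # X is L x 20 (one-hot rows or motif frequency rows)
    XB <- matrix(0, L, 20)
    for (i in 1:L) for (cc in 1:20) {
      acc <- 0
      for (a in 1:20) acc <- acc + X[i, a] * B[a, cc]
      XB[i, cc] <- acc
    }
    E <- matrix(0, L, d_a)
    for (i in 1:L) for (d in 1:d_a) {
      acc <- params$b_embed[d]
      for (cc in 1:20) acc <- acc + XB[i, cc] * params$W_embed[cc, d]
      E[i, d] <- acc
    }
    E
  }
  Em <- embed(motif_matrix)
  enrich <- function(E) {
    H <- matrix(0, K, L)
    for (k in 1:K) for (i in 1:L) {
      acc <- 0
      for (d in 1:d_a) {
        Ck_id <- 0
        for (dd in 1:d_a) Ck_id <- Ck_id + Em[i, dd] * params$W_conv[dd, d, k]
        acc <- acc + Ck_id * E[i, d]
      }
      H[k, i] <- acc
    }
    G <- matrix(0, L, d_p)
    for (i in 1:L) for (p in 1:d_p) {
      acc <- 0
      for (k in 1:K) acc <- acc + params$W_proj[p, k] * H[k, i]
      G[i, p] <- acc
    }
    G
  }
  w <- if (mhc_class == "I") params$w_pos_I else params$w_pos_II
  pool <- function(G) {
    v <- numeric(d_p)
    for (p in 1:d_p) {
      for (i in 1:L) v[p] <- v[p] + w[i] * G[i, p]
    }
    v
  }
  v_wt <- pool(enrich(embed(onehot(wt))))
  v_mt <- pool(enrich(embed(onehot(mt))))
  dist <- 0
  for (p in 1:d_p) dist <- dist + (v_mt[p] - v_wt[p])^2
  dist <- sqrt(dist)
  dir <- (v_mt - v_wt) / (dist + eps)
  u <- c(v_wt, dir)
  hid <- length(params$scale_b1)
  h <- numeric(hid)
  for (j in 1:hid) {
    acc <- params$scale_b1[j]
    for (i in seq_along(u)) acc <- acc + params$scale_W1[i, j] * u[i]
    h[j] <- tanh(acc)
  }
  s <- params$scale_b2
  for (j in 1:hid) s <- s + params$scale_W2[j] * h[j]
  crd <- dist * (1 / (1 + exp(-s)))
  prob <- NA
  if (!is.na(bcov)) {
    logit <- params$W_out[1] * crd + params$W_out[2] * bcov + params$b_out
    prob <- 1 / (1 + exp(-logit))
  }
  list(v_wt = v_wt, v_mt = v_mt, distance = dist, crd = crd, prob = prob)
}

# literal transcription of the published CSiN formula on prefiltered input
oracle_csin <- function(vaf, rank_lists,
                        cutoffs = c(0.375, 0.5, 0.625, 0.75, 1.25, 1.75, 2),
                        vaf_min = 0.05, cap = 500L) {
  keep <- which(vaf >= vaf_min)
  vaf <- vaf[keep]
  rank_lists <- rank_lists[keep]
  if (length(vaf) > cap) {
    ord <- order(vaf, decreasing = TRUE)[1:cap]
    vaf <- vaf[ord]
    rank_lists <- rank_lists[ord]
  }
  n <- length(vaf)
  if (n == 0) return(0)
  q <- sapply(rank_lists, min)
  total <- 0
  used <- 0
  for (cutoff in cutoffs) {
    idx <- which(q < cutoff)
    if (length(idx) == 0) next
    Lval <- sapply(rank_lists[idx], function(r) sum(r < cutoff))
    Vbar <- mean(vaf[idx])
    Lbar <- mean(Lval)
    inner <- 0
    for (j in seq_along(idx)) {
      inner <- inner + (vaf[idx[j]] / Vbar) * (Lval[j] / Lbar)
    }
    total <- total + log(inner / length(idx))
    used <- used + 1
  }
  if (used == 0) 0 else total / used
}

# rank-sum AUROC oracle via the Mann-Whitney statistic
oracle_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  w <- stats::wilcox.test(pos, neg, exact = FALSE)$statistic
  unname(w) / (length(pos) * length(neg))
}
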