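# Two-stage training: contrastive triplet loss on cross-reactive peptide
# triplets (stage 1), then binary cross-entropy fine-tuning on labelled
# epitopes with everything frozen except the scaling network and classifier
# (stage 2). Optimization uses AdamW on the flattened parameter vector.

adamw_state <- function(n) {
  list(m = numeric(n), v = numeric(n), t = 0L)
}

adamw_step <- function(theta, grad, state, lr, mask,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 0.01) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  upd <- lr * (mhat / (sqrt(vhat) + eps) + weight_decay * theta)
  theta[mask] <- theta[mask] - upd[mask]
  list(theta = theta, state = state)
}

# index triplet peptides once; all peptides must be 9-mer cores
# (reduce class II 15-mers to cores with extract_binding_core() beforehand)
index_triplets <- function(triplets, motifs) {
  validate_peptides(c(triplets$seed, triplets$cross_reactive,
                      triplets$non_cross_reactive), lengths = CORE_LENGTH)
  have <- triplets$allele %in% names(motifs)
  if (!all(have)) {
    warning(sum(!have), " triplet(s) skipped: no motif for allele(s) ",
            paste(unique(triplets$allele[!have]), collapse = ", "),
            call. = FALSE)
    triplets <- triplets[have, , drop = FALSE]
  }
  if (nrow(triplets) == 0L) stop("no usable triplets", call. = FALSE)
  list(seed = peptides_to_index_matrix(triplets$seed),
       pos = peptides_to_index_matrix(triplets$cross_reactive),
       neg = peptides_to_index_matrix(triplets$non_cross_reactive),
       allele = triplets$allele, n = nrow(triplets))
}

# mean triplet loss (and optionally gradients) over a set of row indices
triplet_batch <- function(p, cache, ix, rows, margin, env = NULL) {
  total <- 0
  for (r in rows) {
    ce <- cache[[ix$allele[r]]]
    tr_p <- forward_pair(p, ce, ix$seed[r, ], ix$pos[r, ])
    tr_n <- forward_pair(p, ce, ix$seed[r, ], ix$neg[r, ])
    l <- tr_p$crd - tr_n$crd + margin
    if (l > 0) {
      total <- total + l
      if (!is.null(env)) {
        scale <- 1 / length(rows)
        backward_pair(p, ce, tr_p, scale, 0, env)
        backward_pair(p, ce, tr_n, -scale, 0, env)
      }
    }
  }
  total / length(rows)
}

#' Stage-1 contrastive training on cross-reactive triplets
#'
#' Minimizes the triplet loss `max(0, CRD(seed, cross) - CRD(seed, noncross)
#' + margin)` so that cross-reactive pairs sit closer than non-cross-reactive
#' pairs in the peptide embedding space. Triplet peptides must already be
#' 9-mer cores. Training is full-batch up to `batch_cap` triplets and
#' mini-batched beyond it; it is deterministic under a fixed `seed`.
#'
#' @param model An `np_immuno` object (untrained or to continue training).
#' @param triplets Data.frame from [make_triplets()] (columns `seed`,
#'   `cross_reactive`, `non_cross_reactive`, `allele`). Triplets whose
#'   allele has no motif are skipped with a warning.
#' @param motifs Named list of `binding_motif` objects.
#' @param epochs,lr Training schedule (defaults 100 epochs, 0.005, AdamW).
#' @param batch_cap Full-batch threshold (default 4096); above it,
#'   mini-batches of `batch_size`.
#' @param batch_size Mini-batch size (default 512).
#' @param weight_decay AdamW decoupled weight decay.
#' @param seed RNG seed for batch shuffling.
#' @return The model with updated parameters and a `stage1` log holding the
#'   mean triplet loss per epoch.
#' @export
fit_stage1 <- function(model, triplets, motifs, epochs = 100L, lr = 0.005,
                       batch_cap = 4096L, batch_size = 512L,
                       weight_decay = 0.01, seed = 1L) {
  stopifnot(inherits(model, "np_immuno"))
  ix <- index_triplets(triplets, motifs)
  template <- model$params
  theta <- flatten_params(template)
  mask <- trainable_mask(template, stage = 1L)
  state <- adamw_state(length(theta))
  margin <- model$hyper$margin
  losses <- numeric(epochs)
  with_private_seed(seed, {
    for (ep in seq_len(epochs)) {
      model$params <- unflatten_params(theta, template)
      p <- prep_params(model)
      cache <- build_motif_cache(p, motifs[unique(ix$allele)])
      batches <- if (ix$n <= batch_cap) list(seq_len(ix$n)) else {
        split(sample(ix$n), ceiling(seq_len(ix$n) / batch_size))
      }
      ep_loss <- 0
      for (rows in batches) {
        env <- new_grad_env(p)
        ep_loss <- ep_loss + triplet_batch(p, cache, ix, rows, margin, env) *
          length(rows)
        gr <- finalize_grads(env$gr)
        step <- adamw_step(theta, flatten_params(gr), state, lr, mask,
                           weight_decay = weight_decay)
        theta <- step$theta
        state <- step$state
        if (length(batches) > 1L) {
          model$params <- unflatten_params(theta, template)
          p <- prep_params(model)
          cache <- build_motif_cache(p, motifs[unique(ix$allele)])
        }
      }
      losses[ep] <- ep_loss / ix$n
    }
  })
  model$params <- unflatten_params(theta, template)
  model$stage1 <- list(epochs = epochs, lr = lr, loss = losses,
                       n_triplets = ix$n)
  model
}

#' Mean triplet loss of a model on a triplet set
#'
#' @inheritParams fit_stage1
#' @return Mean triplet loss (no gradient).
#' @export
triplet_loss <- function(model, triplets, motifs) {
  ix <- index_triplets(triplets, motifs)
  p <- prep_params(model)
  cache <- build_motif_cache(p, motifs[unique(ix$allele)])
  triplet_batch(p, cache, ix, seq_len(ix$n), model$hyper$margin)
}

#' Geometric distances of seed/cross-reactive and seed/non-cross-reactive
#' pairs in a triplet set
#'
#' Used to assess the separation learned in stage 1 (e.g. by a one-sided
#' Kolmogorov-Smirnov test between the two distance distributions).
#'
#' @inheritParams fit_stage1
#' @return Data.frame with columns `cross` and `noncross` (GeoDist per
#'   triplet).
#' @export
triplet_distances <- function(model, triplets, motifs) {
  ix <- index_triplets(triplets, motifs)
  p <- prep_params(model)
  cache <- build_motif_cache(p, motifs[unique(ix$allele)])
  cross <- noncross <- numeric(ix$n)
  for (r in seq_len(ix$n)) {
    ce <- cache[[ix$allele[r]]]
    cross[r] <- forward_pair(p, ce, ix$seed[r, ], ix$pos[r, ])$dist
    noncross[r] <- forward_pair(p, ce, ix$seed[r, ], ix$neg[r, ])$dist
  }
  data.frame(cross = cross, noncross = noncross)
}

#' Stage-2 fine-tuning on labelled epitopes
#'
#' Fine-tunes the classifier on T-cell assay labels with binary
#' cross-entropy. All representation layers (residue embedding, kernels,
#' projection, position weights) are frozen; only the scaling network and
#' the output classifier move. Because the frozen layers fix the geometric
#' representation, the per-sample distance, origin and direction are
#' precomputed once and training is fully vectorized. The epoch with the
#' lowest validation loss is kept when a validation split is present.
#'
#' @param model An `np_immuno` object, normally after [fit_stage1()].
#' @param epitopes Data.frame with columns `wt_core`, `mt_core`, `allele`,
#'   `label` (0/1), optionally `split` (`"train"`/`"val"`/`"test"`; absent
#'   means all rows train) and `rank_percentile` (mutant binding rank for
#'   the covariate; required unless `ranks` given).
#' @param motifs Named list of `binding_motif` objects.
#' @param ranks Optional numeric vector overriding
#'   `epitopes$rank_percentile`.
#' @param epochs,lr,weight_decay Training schedule (defaults 100, 0.005,
#'   AdamW).
#' @return The model with updated scaling/classifier parameters and a
#'   `stage2` log (train and validation BCE per epoch, selected epoch).
#' @export
fit_stage2 <- function(model, epitopes, motifs, ranks = NULL, epochs = 100L,
                       lr = 0.005, weight_decay = 0.01) {
  stopifnot(inherits(model, "np_immuno"))
  need <- c("wt_core", "mt_core", "allele", "label")
  stopifnot(all(need %in% names(epitopes)))
  if (is.null(ranks)) {
    if (!"rank_percentile" %in% names(epitopes)) {
      stop("supply `ranks` or a rank_percentile column", call. = FALSE)
    }
    ranks <- epitopes$rank_percentile
  }
  split <- if ("split" %in% names(epitopes)) epitopes$split else {
    rep("train", nrow(epitopes))
  }
  train_rows <- which(split == "train")
  val_rows <- which(split == "val")
  y <- epitopes$label
  if (length(unique(y[train_rows])) < 2L) {
    stop("training labels are single-class; cannot fit the classifier",
         call. = FALSE)
  }
  # frozen upstream: precompute distance and [origin; direction] per sample
  p <- prep_params(model)
  cache <- build_motif_cache(p, motifs[unique(epitopes$allele)])
  n <- nrow(epitopes)
  d_p <- model$hyper$d_p
  U <- matrix(0, n, 2 * d_p)
  dist <- numeric(n)
  bcov <- numeric(n)
  for (i in seq_len(n)) {
    ce <- cache[[epitopes$allele[i]]]
    tr <- forward_pair(p, ce, peptide_to_indices(epitopes$wt_core[i]),
                       peptide_to_indices(epitopes$mt_core[i]))
    U[i, ] <- tr$u
    dist[i] <- tr$dist
    bcov[i] <- binding_covariate(ranks[i], ce$mhc_class)
  }
  frozen_before <- model$params[c("W_embed", "b_embed", "W_conv", "W_proj",
                                  "w_pos_I", "w_pos_II")]
  template <- model$params
  theta <- flatten_params(template)
  mask <- trainable_mask(template, stage = 2L)
  state <- adamw_state(length(theta))
  # prob is already aligned with `rows`
  bce <- function(prob, rows) {
    pr <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
    -mean(y[rows] * log(pr) + (1 - y[rows]) * log(1 - pr))
  }
  fwd <- function(pars, rows) {
    Z1 <- sweep(U[rows, , drop = FALSE] %*% pars$scale_W1, 2,
                pars$scale_b1, `+`)
    Hh <- tanh(Z1)
    s <- as.vector(Hh %*% pars$scale_W2) + pars$scale_b2
    sig_s <- sigmoid(s)
    crd <- dist[rows] * sig_s
    logit <- pars$W_out[1] * crd + pars$W_out[2] * bcov[rows] + pars$b_out
    list(Hh = Hh, sig_s = sig_s, crd = crd, prob = sigmoid(logit))
  }
  train_log <- val_log <- numeric(epochs)
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  for (ep in seq_len(epochs)) {
    pars <- unflatten_params(theta, template)
    f <- fwd(pars, train_rows)
    m <- length(train_rows)
    g_logit <- (f$prob - y[train_rows]) / m
    gr <- zero_grads(template)
    gr$W_out <- c(sum(g_logit * f$crd), sum(g_logit * bcov[train_rows]))
    gr$b_out <- sum(g_logit)
    g_crd <- g_logit * pars$W_out[1]
    g_s <- g_crd * dist[train_rows] * f$sig_s * (1 - f$sig_s)
    gr$scale_W2 <- as.vector(crossprod(f$Hh, g_s))
    gr$scale_b2 <- sum(g_s)
    gHh <- outer(g_s, pars$scale_W2)
    gZ1 <- gHh * (1 - f$Hh^2)
    gr$scale_W1 <- crossprod(U[train_rows, , drop = FALSE], gZ1)
    gr$scale_b1 <- colSums(gZ1)
    step <- adamw_step(theta, flatten_params(gr), state, lr, mask,
                       weight_decay = weight_decay)
    theta <- step$theta
    state <- step$state
    pars <- unflatten_params(theta, template)
    train_log[ep] <- bce(fwd(pars, train_rows)$prob, train_rows)
    if (length(val_rows) > 0L) {
      val_log[ep] <- bce(fwd(pars, val_rows)$prob, val_rows)
      if (val_log[ep] < best$loss) {
        best <- list(loss = val_log[ep], theta = theta, epoch = ep)
      }
    }
  }
  if (length(val_rows) > 0L) theta <- best$theta
  model$params <- unflatten_params(theta, template)
  frozen_after <- model$params[names(frozen_before)]
  stopifnot(identical(frozen_before, frozen_after))
  model$stage2 <- list(epochs = epochs, lr = lr, train_loss = train_log,
                       val_loss = if (length(val_rows)) val_log else NULL,
                       selected_epoch = if (length(val_rows)) best$epoch
                       else epochs,
                       n_train = length(train_rows), n_val = length(val_rows))
  model
}

# ---- S3 methods ----------------------------------------------------------

#' @export
print.np_immuno <- function(x, ...) {
  h <- x$hyper
  cat("cross-reactivity-distance immunogenicity model\n")
  cat(sprintf("  residue dim %d, peptide dim %d, %d kernels, core length %d\n",
              h$d_a, h$d_p, h$K, h$L))
  cat("  stage 1:", if (is.null(x$stage1)) "untrained" else
    sprintf("%d epochs on %d triplets (final loss %.4f)",
            x$stage1$epochs, x$stage1$n_triplets,
            utils::tail(x$stage1$loss, 1)), "\n")
  cat("  stage 2:", if (is.null(x$stage2)) "untrained" else
    sprintf("%d epochs on %d epitopes (final train BCE %.4f)",
            x$stage2$epochs, x$stage2$n_train,
            utils::tail(x$stage2$train_loss, 1)), "\n")
  invisible(x)
}

#' @export
summary.np_immuno <- function(object, ...) {
  print(object)
  wI <- object$params$w_pos_I
  wII <- object$params$w_pos_II
  cat("  position factors (MHC-I, normalized): ",
      paste(sprintf("%.2f", abs(wI) / sum(abs(wI))), collapse = " "), "\n")
  cat("  position factors (MHC-II, normalized):",
      paste(sprintf("%.2f", abs(wII) / sum(abs(wII))), collapse = " "), "\n")
  invisible(object)
}

#' @export
coef.np_immuno <- function(object, ...) {
  object$params
}

#' Plot residue embeddings of a trained model
#'
#' Scatter of the 20 canonical residues in the 2-D residue embedding space
#' (the first two embedding dimensions when d_a > 2).
#'
#' @param x An `np_immuno` object.
#' @param ... Passed to [plot()].
#' @export
plot.np_immuno <- function(x, ...) {
  Emb <- residue_embedding_table(x$params)
  plot(Emb[, 1], Emb[, 2], type = "n",
       xlab = "embedding dim 1", ylab = "embedding dim 2",
       main = "residue embeddings", ...)
  graphics::text(Emb[, 1], Emb[, 2], labels = AA_ALPHABET)
  invisible(x)
}
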