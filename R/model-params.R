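# Parameter container for the cross-reactivity-distance network, plus
# flatten/unflatten helpers used by the optimizer and JSON checkpointing.
#
# Architecture (all dimensions configurable, defaults in parentheses):
#   residue transform: one-hot -> BLOSUM62 row -> affine map to d_a (2)
#   motif enrichment:  K (8) convolutional kernels d_a x d_a modulated by the
#                      motif embedding, projected to d_p (2)
#   pooling:           learnable per-position weights over the L (9) core
#                      positions, separate for MHC-I and MHC-II
#   scaling:           two-layer tanh network (hidden 8) on [origin; direction]
#   classifier:        logistic on [CRD; binding covariate]

#' Initialize the immunogenicity model
#'
#' Creates an untrained model object holding all trainable tensors and
#' hyperparameters. Weights are drawn from N(0, init_sd) under a private RNG
#' stream; position weights start uniform at 1/L.
#'
#' @param d_a Residue embedding dimension (default 2).
#' @param d_p Peptide embedding dimension (default 2).
#' @param K Number of convolutional kernels (default 8).
#' @param hidden Hidden width of the scaling network (default 8).
#' @param epsilon Stabilizer in the direction normalization (default 1e-8).
#' @param margin Triplet-loss margin (default 1).
#' @param init_sd Standard deviation of the weight initialization.
#' @param seed Seed of the private initialization stream.
#' @return An object of class `np_immuno`.
#' @export
immuno_model <- function(d_a = 2L, d_p = 2L, K = 8L, hidden = 8L,
                         epsilon = 1e-8, margin = 1, init_sd = 0.1,
                         seed = 1L) {
  L <- CORE_LENGTH
  params <- with_private_seed(seed, list(
    W_embed  = matrix(stats::rnorm(20 * d_a, sd = init_sd), 20, d_a),
    b_embed  = stats::rnorm(d_a, sd = init_sd),
    W_conv   = array(stats::rnorm(d_a * d_a * K, sd = init_sd),
                     dim = c(d_a, d_a, K)),
    W_proj   = matrix(stats::rnorm(d_p * K, sd = init_sd), d_p, K),
    w_pos_I  = rep(1 / L, L),
    w_pos_II = rep(1 / L, L),
    scale_W1 = matrix(stats::rnorm(2 * d_p * hidden, sd = init_sd),
                      2 * d_p, hidden),
    scale_b1 = rep(0, hidden),
    scale_W2 = stats::rnorm(hidden, sd = init_sd),
    scale_b2 = 0,
    W_out    = c(1, 1),
    b_out    = 0))
  structure(
    list(params = params,
         hyper = list(d_a = as.integer(d_a), d_p = as.integer(d_p),
                      K = as.integer(K), L = L, hidden = as.integer(hidden),
                      epsilon = epsilon, margin = margin),
         stage1 = NULL, stage2 = NULL),
    class = "np_immuno")
}

# ---- flatten / unflatten -------------------------------------------------

param_dims <- function(params) lapply(params, function(p) dim(p) %||% length(p))

`%||%` <- function(a, b) if (is.null(a)) b else a

flatten_params <- function(params) unlist(params, use.names = FALSE)

unflatten_params <- function(flat, template) {
  out <- template
  at <- 0L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    v <- flat[at + seq_len(n)]
    if (!is.null(dim(template[[nm]]))) dim(v) <- dim(template[[nm]])
    out[[nm]] <- v
    at <- at + n
  }
  stopifnot(at == length(flat))
  out
}

# logical mask over the flattened vector selecting trainable entries
trainable_mask <- function(params, stage) {
  stage2_free <- c("scale_W1", "scale_b1", "scale_W2", "scale_b2",
                   "W_out", "b_out")
  unlist(lapply(names(params), function(nm) {
    rep(stage == 1L || nm %in% stage2_free, length(params[[nm]]))
  }))
}

# fresh zero-valued gradient accumulator matching `params`
zero_grads <- function(params) lapply(params, function(p) p * 0)

# ---- checkpointing -------------------------------------------------------

#' Save a model checkpoint
#'
#' Writes all tensors, hyperparameters and training logs to a single JSON
#' file (versioned schema).
#'
#' @param model An `np_immuno` object.
#' @param path Output path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "np_immuno"))
  payload <- list(
    schema = "np_immuno/1",
    hyper = model$hyper,
    dims = param_dims(model$params),
    params = lapply(model$params, as.vector),
    stage1 = model$stage1, stage2 = model$stage2)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
}

#' Load a model checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return An `np_immuno` object.
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, "np_immuno/1")) {
    stop("unrecognized checkpoint schema", call. = FALSE)
  }
  params <- payload$params
  for (nm in names(params)) {
    d <- payload$dims[[nm]]
    if (length(d) > 1L) dim(params[[nm]]) <- d
  }
  structure(list(params = params, hyper = as.list(payload$hyper),
                 stage1 = payload$stage1, stage2 = payload$stage2),
            class = "np_immuno")
}
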