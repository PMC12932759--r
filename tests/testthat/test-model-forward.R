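# Forward pass of the cross-reactivity-distance network against independent
# loop-based oracles, analytic-gradient verification, and the component
# score decomposition.

test_that("residue transform reproduces BLOSUM62 rows under a selector map", {
  model <- ts_model()
  # embed weights selecting the first two BLOSUM62 columns (A, R), zero bias
  model$params$W_embed[] <- 0
  model$params$W_embed[1, 1] <- 1
  model$params$W_embed[2, 2] <- 1
  model$params$b_embed[] <- 0
  Emb <- residue_embedding(model)
  expect_equal(unname(Emb["A", ]), c(4, -1))  # BLOSUM62 row A at (A, R)
  # affine map: a 50/50 motif row embeds at the midpoint of A and C
  motif <- motif_from_cores(c("AAAAAAAAA", "CCCCCCCCC"), "MIX", "I")
  p <- neoscape:::prep_params(model)
  ce <- neoscape:::motif_cache_entry(p, motif)
  expect_equal(ce$Em[1, ], (Emb["A", ] + Emb["C", ]) / 2)
})

test_that("forward pass matches the loop-based oracle to 1e-10", {
  world <- ts_world()
  set.seed(31)
  for (i in 1:25) {
    model <- immuno_model(init_sd = 0.5, seed = 1000 + i)
    allele <- sample(names(world$motifs), 1)
    motif <- world$motifs[[allele]]
    wt <- random_peptidome(1, 9)
    res <- strsplit(wt, "")[[1]]
    pos <- sample(9, 1)
    res[pos] <- sample(AA_ALPHABET, 1)
    mt <- paste(res, collapse = "")
    bcov <- runif(1)
    p <- neoscape:::prep_params(model)
    ce <- neoscape:::motif_cache_entry(p, motif)
    tr <- neoscape:::forward_pair(
      p, ce, neoscape:::peptide_to_indices(wt),
      neoscape:::peptide_to_indices(mt), bcov)
    orc <- oracle_forward(model$params, motif$matrix, wt, mt,
                          motif$mhc_class, bcov,
                          eps = model$hyper$epsilon)
    expect_equal(tr$wt$v, orc$v_wt, tolerance = 1e-10)
    expect_equal(tr$dist, orc$distance, tolerance = 1e-10)
    expect_equal(tr$crd, orc$crd, tolerance = 1e-10)
    expect_equal(tr$prob, orc$prob, tolerance = 1e-10)
  }
})

test_that("geometric representation and scaling obey their closed forms", {
  world <- ts_world()
  motif <- world$motifs[[1]]
  model <- ts_model()

  # self-pair: distance, direction and CRD all vanish; probability reduces
  # to the covariate-only classifier
  trc <- forward_trace(model, list(wt_core = "KLVALGINA",
                                   mt_core = "KLVALGINA"),
                       motif, binding_rank = 1)
  expect_equal(trc$distance, 0)
  expect_equal(trc$crd, 0)
  expect_equal(trc$direction, c(0, 0))
  b <- binding_covariate(1, "I")
  expect_equal(trc$probability,
               1 / (1 + exp(-(model$params$W_out[2] * b +
                                model$params$b_out))))

  # scale net forced to zero: CRD = distance / 2 (sigmoid(0) = 1/2)
  m0 <- ts_model()
  m0$params$scale_W2[] <- 0
  m0$params$scale_b2 <- 0
  t0 <- forward_trace(m0, list(wt_core = "KLVALGINA",
                               mt_core = "KLVALGINW"), motif)
  expect_gt(t0$distance, 0)
  expect_equal(t0$crd, t0$distance / 2)

  # zero classifier: probability 1/2 regardless of input
  mz <- ts_model()
  mz$params$W_out[] <- 0
  mz$params$b_out <- 0
  tz <- forward_trace(mz, list(wt_core = "KLVALGINA",
                               mt_core = "KLVALGINW"), motif,
                      binding_rank = 0.3)
  expect_equal(tz$probability, 0.5)
})

test_that("CRD is bounded by the geometric distance on random inputs", {
  world <- ts_world()
  set.seed(77)
  for (i in 1:40) {
    model <- immuno_model(init_sd = runif(1, 0.05, 1), seed = 200 + i)
    motif <- world$motifs[[sample(length(world$motifs), 1)]]
    wt <- random_peptidome(1, 9)
    res <- strsplit(wt, "")[[1]]
    pos <- sample(9, 1)
    res[pos] <- sample(AA_ALPHABET, 1)
    trc <- forward_trace(model, list(wt_core = wt,
                                     mt_core = paste(res, collapse = "")),
                         motif)
    expect_gte(trc$crd, 0)
    expect_lte(trc$crd, trc$distance)
    if (trc$distance > 0) expect_lt(trc$crd, trc$distance)
  }
})

test_that("analytic gradients match central finite differences", {
  world <- ts_world()
  tab <- gen_tcr_binding_table(ts_cfg(), world, seed = 7)
  tri <- make_triplets(tab, world$predictor, seed = 5)[1:6, ]
  model <- immuno_model(init_sd = 0.4, seed = 9)
  ix <- neoscape:::index_triplets(tri, world$motifs)
  template <- model$params
  theta <- neoscape:::flatten_params(template)
  loss_at <- function(th) {
    m2 <- model
    m2$params <- neoscape:::unflatten_params(th, template)
    p <- neoscape:::prep_params(m2)
    cache <- neoscape:::build_motif_cache(p, world$motifs[unique(ix$allele)])
    neoscape:::triplet_batch(p, cache, ix, seq_len(ix$n), model$hyper$margin)
  }
  p <- neoscape:::prep_params(model)
  cache <- neoscape:::build_motif_cache(p, world$motifs[unique(ix$allele)])
  env <- neoscape:::new_grad_env(p)
  neoscape:::triplet_batch(p, cache, ix, seq_len(ix$n), model$hyper$margin,
                           env)
  ga <- neoscape:::flatten_params(neoscape:::finalize_grads(env$gr))
  h <- 1e-6
  set.seed(12)
  probe <- sample(length(theta), 30)
  for (j in probe) {
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    expect_equal(ga[j], (loss_at(up) - loss_at(dn)) / (2 * h),
                 tolerance = 1e-4)
  }
})

test_that("component scores decompose as defined", {
  world <- ts_world()
  motif <- world$motifs[[1]]
  model <- ts_model()

  self <- component_scores(model, list(wt_core = "KLVALGINA",
                                       mt_core = "KLVALGINA"), motif)
  expect_equal(unname(self), c(0, 0, 0, 0))

  pair <- list(wt_core = "KLVALGINA", mt_core = "KLVALGINW")
  cs <- component_scores(model, pair, motif)
  # position weights start uniform at 1/9: SubPosDist = SubDist / 9
  expect_equal(cs[["SubPosDist"]], cs[["SubDist"]] / 9)
  # GeoDist is definitionally the trace distance; CRD its scaled version
  trc <- forward_trace(model, pair, motif)
  expect_equal(cs[["GeoDist"]], trc$distance)
  expect_equal(cs[["CRD"]], trc$crd)
  expect_lte(cs[["CRD"]], cs[["GeoDist"]])
})

test_that("motif-enriched residue embeddings match the residue-wise oracle", {
  world <- ts_world()
  motif <- world$motifs[[2]]
  model <- immuno_model(init_sd = 0.5, seed = 33)
  pos <- 4L
  emb <- motif_enriched_residue_embedding(model, motif, pos)
  # oracle: run each residue through the full forward machinery at `pos`
  for (aa in c("A", "W", "P", "V")) {
    pep <- paste(rep(aa, 9), collapse = "")
    # a one-hot position weight at `pos` pools exactly the enriched row
    m2 <- model
    m2$params$w_pos_I <- as.numeric(seq_len(9) == pos)
    orc2 <- oracle_forward(m2$params, motif$matrix, pep, pep, "I")
    expect_equal(unname(emb[aa, ]), orc2$v_wt, tolerance = 1e-10)
  }
  # identical motifs give identical enriched embeddings
  motif_copy <- motif
  motif_copy$allele <- "COPY"
  expect_equal(motif_enriched_residue_embedding(model, motif_copy, pos), emb)
})
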