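# Synthetic-data generators producing every input the framework consumes:
# position-weight-matrix alleles with anchor structure, TCR-pMHC binding
# tables with planted cross-reactive groups, labelled substitution datasets
# with a controllable ground-truth effect size, and patient cohorts with
# clonal/subclonal cluster architecture.
#
# The ground-truth immunogenicity distance used for labels is defined on
# BLOSUM62 PCA embeddings, not on the model's own embeddings, so recovery
# tests cannot be circular.

#' Synthetic-data configuration
#'
#' Bundles the dials of all generators with defaults emulating the shape of
#' curated TCR-pMHC binding tables, T-cell assay epitope sets and
#' clonality-annotated cohorts.
#'
#' @param n_alleles_i,n_alleles_ii Alleles per MHC class.
#' @param sharpness Motif sharpness: Dirichlet rows use concentration
#'   `1/sharpness` (higher = sharper; `Inf` = one-hot rows). Anchor
#'   positions are drawn 20x sharper.
#' @param anchor_positions_i,anchor_positions_ii Anchor positions of the
#'   generated class I / class II PWMs.
#' @param n_tcr_groups Number of (allele, CDR3) groups in the binding table.
#' @param group_size_range Peptides per group (uniform draw).
#' @param n_epitopes Labelled substitution records.
#' @param beta,gamma Label-model weights on the ground-truth substitution
#'   distance and on binding strength.
#' @param n_patients Cohort size.
#' @param max_clusters Clusters per patient (uniform 1..max, always
#'   including a clonal cluster at prevalence 1).
#' @param mutations_per_cluster_mu,mutations_per_cluster_size Negative
#'   binomial mean/size for cluster mutation counts (floored at 1).
#' @param purity Tumor purity in the VAF model
#'   `VAF = 0.5 * prevalence * purity` plus Beta noise.
#' @param binder_fraction Fraction of cohort mutations whose wild-type
#'   peptide is drawn from its allele's PWM (strong binders); the rest are
#'   uniform random peptides.
#' @param response_effect Logistic effect size linking the summed landscape
#'   score to the simulated response label.
#' @param peptidome_n Peptidome sample size used when building motifs.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_alleles_i = 3L, n_alleles_ii = 2L,
                             sharpness = 4, anchor_positions_i = c(2L, 9L),
                             anchor_positions_ii = c(1L, 4L, 6L, 9L),
                             n_tcr_groups = 60L, group_size_range = c(2L, 4L),
                             n_epitopes = 300L, beta = 1, gamma = 1,
                             n_patients = 30L, max_clusters = 6L,
                             mutations_per_cluster_mu = 12,
                             mutations_per_cluster_size = 4,
                             purity = 0.7, response_effect = 1.5,
                             binder_fraction = 0.5, peptidome_n = 3000L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_alleles_i >= 1L, cfg$n_alleles_ii >= 1L,
            cfg$n_tcr_groups >= 0L, cfg$n_patients >= 1L,
            cfg$max_clusters >= 1L, cfg$purity > 0, cfg$purity <= 1)
  class(cfg) <- "synthetic_config"
  cfg
}

# one Dirichlet-distributed PWM row (concentration alpha, sharper = smaller)
rdirichlet_row <- function(alpha) {
  g <- stats::rgamma(20L, shape = alpha)
  if (sum(g) == 0) g[sample.int(20L, 1L)] <- 1
  g / sum(g)
}

gen_pwm <- function(sharpness, anchors) {
  if (is.infinite(sharpness)) {
    m <- matrix(0, CORE_LENGTH, 20L)
    m[cbind(seq_len(CORE_LENGTH), sample.int(20L, CORE_LENGTH, TRUE))] <- 1
  } else {
    alpha <- 1 / sharpness
    m <- t(vapply(seq_len(CORE_LENGTH), function(i) {
      rdirichlet_row(if (i %in% anchors) alpha / 20 else alpha)
    }, numeric(20L)))
  }
  colnames(m) <- AA_ALPHABET
  m
}

#' Generate synthetic alleles, predictors and binding motifs
#'
#' Draws per-allele sharp PWMs with designated anchor positions, wraps them
#' in a deterministic [pwm_predictor()], and builds each allele's binding
#' motif from a uniform random peptidome sample.
#'
#' @param config A [synthetic_config()].
#' @param seed RNG seed.
#' @return List with `predictor`, `motifs` (named list of `binding_motif`),
#'   `pwms`, `alleles_i`, `alleles_ii`.
#' @export
gen_alleles_and_motifs <- function(config = synthetic_config(), seed = 1L) {
  alleles_i <- sprintf("SYN-I*%02d", seq_len(config$n_alleles_i))
  alleles_ii <- sprintf("SYN-II*%02d", seq_len(config$n_alleles_ii))
  with_private_seed(seed, {
    pwms <- c(
      stats::setNames(lapply(alleles_i, function(a) {
        gen_pwm(config$sharpness, config$anchor_positions_i)
      }), alleles_i),
      stats::setNames(lapply(alleles_ii, function(a) {
        gen_pwm(config$sharpness, config$anchor_positions_ii)
      }), alleles_ii))
    classes <- stats::setNames(rep(c("I", "II"),
                                   c(length(alleles_i), length(alleles_ii))),
                               c(alleles_i, alleles_ii))
    predictor <- pwm_predictor(pwms, mhc_class = classes)
    motifs <- lapply(names(pwms), function(a) {
      len <- if (classes[[a]] == "I") 9L else 15L
      build_binding_motif(random_peptidome(config$peptidome_n, len),
                          a, predictor)
    })
    names(motifs) <- names(pwms)
    list(predictor = predictor, motifs = motifs, pwms = pwms,
         alleles_i = alleles_i, alleles_ii = alleles_ii)
  })
}

# sample a strong binder for one allele by drawing each position from the PWM
sample_binder <- function(pwm) {
  paste(vapply(seq_len(CORE_LENGTH), function(i) {
    sample(AA_ALPHABET, 1L, prob = pwm[i, ] + 1e-4)
  }, character(1)), collapse = "")
}

# conservative (BLOSUM62-positive) single substitution away from anchors
conservative_variant <- function(peptide, anchors) {
  positions <- setdiff(seq_len(CORE_LENGTH), anchors)
  B <- blosum62()
  res <- strsplit(peptide, "")[[1]]
  for (pos in sample(positions)) {
    opts <- AA_ALPHABET[B[res[pos], ] > 0 & AA_ALPHABET != res[pos]]
    if (length(opts) > 0L) {
      res[pos] <- sample(opts, 1L)
      return(paste(res, collapse = ""))
    }
  }
  NA_character_
}

#' Generate a TCR-pMHC binding table with planted cross-reactive structure
#'
#' Each (allele, CDR3) group holds a PWM-sampled seed binder plus
#' conservative single-substitution variants at non-anchor positions, so
#' every within-group peptide pair is cross-reactive by construction. The
#' planted ordered Hamming-1 pair list is attached as attribute
#' `"true_pairs"`.
#'
#' @param config A [synthetic_config()].
#' @param world Output of [gen_alleles_and_motifs()].
#' @param seed RNG seed.
#' @return Data.frame with columns `cdr3_beta`, `peptide`, `allele`,
#'   `mhc_class` (class I groups only; triplet peptides are 9-mer cores).
#' @export
gen_tcr_binding_table <- function(config = synthetic_config(), world,
                                  seed = 1L) {
  if (config$n_tcr_groups == 0L) {
    out <- data.frame(cdr3_beta = character(0), peptide = character(0),
                      allele = character(0), mhc_class = character(0))
    attr(out, "true_pairs") <- data.frame(seed = character(0),
                                          cross_reactive = character(0),
                                          allele = character(0))
    return(out)
  }
  with_private_seed(seed, {
    rows <- list()
    pairs <- list()
    for (g in seq_len(config$n_tcr_groups)) {
      allele <- sample(world$alleles_i, 1L)
      pwm <- world$pwms[[allele]]
      cdr3 <- paste0("CASS", paste(sample(AA_ALPHABET, 8L, TRUE),
                                   collapse = ""))
      size <- sample(seq(config$group_size_range[1],
                         config$group_size_range[2]), 1L)
      seed_pep <- sample_binder(pwm)
      peps <- seed_pep
      while (length(peps) < size) {
        v <- conservative_variant(seed_pep, config$anchor_positions_i)
        if (!is.na(v)) peps <- unique(c(peps, v))
        else break
      }
      for (p in peps) {
        rows[[length(rows) + 1L]] <- data.frame(
          cdr3_beta = cdr3, peptide = p, allele = allele, mhc_class = "I",
          stringsAsFactors = FALSE)
      }
      for (i in seq_along(peps)) {
        for (j in seq_along(peps)) {
          if (i != j && hamming(peps[i], peps[j]) == 1L) {
            pairs[[length(pairs) + 1L]] <- data.frame(
              seed = peps[i], cross_reactive = peps[j], allele = allele,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    out <- do.call(rbind, rows)
    tp <- do.call(rbind, pairs)
    attr(out, "true_pairs") <- tp[!duplicated(tp), ]
    out
  })
}

#' Generate labelled wild-type/mutant epitopes with known truth
#'
#' Wild-type 9-mer binders are PWM-sampled; the mutant substitutes one
#' random position with a random different residue. Labels are Bernoulli
#' draws from a logistic model on the ground-truth substitution distance
#' and the binding strength, `sigmoid(beta * (d - mean d) + gamma *
#' (b - mean b))`: `d` is the Euclidean distance between the two residues
#' in the 2-D BLOSUM62 PCA embedding, `b` the [binding_covariate()] of the
#' mutant rank. Both covariates are centered within the generated set so
#' label prevalence stays near 1/2 at any effect size (and is exactly
#' balanced in expectation at `beta = gamma = 0`).
#'
#' @param config A [synthetic_config()].
#' @param world Output of [gen_alleles_and_motifs()].
#' @param seed RNG seed.
#' @return Data.frame with columns `wt_core`, `mt_core`, `allele`,
#'   `mhc_class`, `rank_percentile`, `true_distance`, `label`.
#' @export
gen_labeled_epitopes <- function(config = synthetic_config(), world,
                                 seed = 1L) {
  pca <- pca_embedding(blosum62())
  with_private_seed(seed, {
    allele <- sample(world$alleles_i, config$n_epitopes, replace = TRUE)
    wt <- vapply(allele, function(a) sample_binder(world$pwms[[a]]),
                 character(1), USE.NAMES = FALSE)
    pos <- sample.int(CORE_LENGTH, config$n_epitopes, replace = TRUE)
    mt <- wt
    true_dist <- numeric(config$n_epitopes)
    for (i in seq_len(config$n_epitopes)) {
      res <- strsplit(wt[i], "")[[1]]
      new_res <- sample(setdiff(AA_ALPHABET, res[pos[i]]), 1L)
      true_dist[i] <- sqrt(sum((pca[res[pos[i]], ] - pca[new_res, ])^2))
      res[pos[i]] <- new_res
      mt[i] <- paste(res, collapse = "")
    }
    rank <- unlist(lapply(unique(allele), function(a) {
      stats::setNames(
        predict_binding(world$predictor, mt[allele == a], a)$rank_percentile,
        which(allele == a))
    }))
    rank <- rank[order(as.integer(names(rank)))]
    bcov <- binding_covariate(rank, "I")
    p <- sigmoid(config$beta * (true_dist - mean(true_dist)) +
                   config$gamma * (bcov - mean(bcov)))
    data.frame(wt_core = wt, mt_core = mt, allele = allele, mhc_class = "I",
               rank_percentile = unname(rank), true_distance = true_dist,
               label = stats::rbinom(config$n_epitopes, 1L, p),
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic tumor cohort with known clonal architecture
#'
#' Each patient receives a clonal cluster at prevalence 1 plus subclones
#' with Beta(2, 3) prevalences; cluster mutation counts are negative
#' binomial (floored at 1); per-mutation CCF equals cluster prevalence and
#' `VAF = 0.5 * CCF * purity` with Beta noise. Per-allele binding ranks and
#' pMHC rank lists are generated from the mock predictors on PWM-derived
#' wild-type/mutant cores. Immunogenicity scores come from `score_fun`,
#' called once per patient; the default draws a per-patient antigen quality
#' q ~ Uniform(0.2, 0.8) and then per-mutation Beta(4q, 4(1-q)) scores, so
#' tumors differ in neoantigen quality independently of their burden (and
#' the summed landscape score is not a mere transform of the mutation
#' count). A response label is simulated from a logistic model on the
#' standardized summed landscape score and attached as attribute
#' `"response"` alongside attribute `"truth"`.
#'
#' @param config A [synthetic_config()].
#' @param world Output of [gen_alleles_and_motifs()].
#' @param score_fun Optional `function(n)` returning a data.frame or list
#'   with `np_immuno_i` and `np_immuno_ii` vectors of length n.
#' @param seed RNG seed.
#' @return List of [tumor_profile()] objects with attributes `"response"`
#'   (0/1 per patient) and `"truth"` (generator internals).
#' @export
gen_cohort <- function(config = synthetic_config(), world, score_fun = NULL,
                       seed = 1L) {
  if (is.null(score_fun)) {
    score_fun <- function(n) {
      q <- stats::runif(1, 0.2, 0.8)  # per-tumor antigen quality
      list(np_immuno_i = stats::rbeta(n, 4 * q, 4 * (1 - q)),
           np_immuno_ii = stats::rbeta(n, 4 * q, 4 * (1 - q)))
    }
  }
  with_private_seed(seed, {
    profiles <- vector("list", config$n_patients)
    for (pt in seq_len(config$n_patients)) {
      hla_i <- sample(world$alleles_i, min(3L, length(world$alleles_i)))
      hla_ii <- sample(world$alleles_ii, min(2L, length(world$alleles_ii)))
      n_cl <- sample.int(config$max_clusters, 1L)
      prev <- c(1, sort(stats::rbeta(n_cl - 1L, 2, 3), decreasing = TRUE))
      clusters <- data.frame(cluster_id = paste0("C", seq_len(n_cl)),
                             prevalence = prev)
      counts <- pmax(1L, stats::rnbinom(n_cl,
                                        size = config$mutations_per_cluster_size,
                                        mu = config$mutations_per_cluster_mu))
      # keep at least 4 mutations so per-patient quartiles are well defined
      if (sum(counts) < 4L) counts[1] <- counts[1] + 4L - sum(counts)
      n_mut <- sum(counts)
      cluster_id <- rep(clusters$cluster_id, counts)
      ccf <- rep(prev, counts)
      noise <- stats::rbeta(n_mut, 5, 5) - 0.5
      vaf <- pmin(1, pmax(0.01, 0.5 * ccf * config$purity + 0.1 * noise))
      allele_mut <- sample(hla_i, n_mut, replace = TRUE)
      is_binder <- stats::runif(n_mut) < config$binder_fraction
      wt <- character(n_mut)
      wt[is_binder] <- vapply(allele_mut[is_binder], function(a) {
        sample_binder(world$pwms[[a]])
      }, character(1), USE.NAMES = FALSE)
      if (any(!is_binder)) {
        wt[!is_binder] <- random_peptidome(sum(!is_binder), CORE_LENGTH)
      }
      mt <- vapply(wt, function(p) {
        res <- strsplit(p, "")[[1]]
        pos <- sample.int(CORE_LENGTH, 1L)
        res[pos] <- sample(setdiff(AA_ALPHABET, res[pos]), 1L)
        paste(res, collapse = "")
      }, character(1), USE.NAMES = FALSE)
      rank_mat <- vapply(hla_i, function(a) {
        predict_binding(world$predictor, mt, a)$rank_percentile
      }, numeric(n_mut))
      rank_mat <- matrix(rank_mat, nrow = n_mut,
                         dimnames = list(NULL, hla_i))
      ranks_i <- lapply(seq_len(n_mut), function(i) rank_mat[i, ])
      ranks_ii <- lapply(seq_len(n_mut), function(i) {
        # class II ranks drawn, not predicted: 9-mer cores on class II
        # motifs would not exercise the 15-mer path meaningfully
        stats::setNames(10^stats::runif(length(hla_ii), -0.5, 1.6), hla_ii)
      })
      scores <- score_fun(n_mut)
      mutations <- data.frame(
        mutation_id = sprintf("P%02d_M%04d", pt, seq_len(n_mut)),
        gene = sprintf("GENE%03d", sample.int(400L, n_mut, TRUE)),
        wt_core = wt, mt_core = mt, allele = allele_mut,
        dna_af = vaf, rna_af = pmin(1, pmax(0, vaf + 0.05 * noise)),
        tpm = stats::rlnorm(n_mut, 2, 1.2),
        vaf = vaf, ccf = ccf, cluster_id = cluster_id,
        np_immuno_i = scores$np_immuno_i, np_immuno_ii = scores$np_immuno_ii,
        stringsAsFactors = FALSE)
      mutations$phbr_i <- vapply(ranks_i, phbr, numeric(1))
      mutations$rank_list_i <- ranks_i
      mutations$rank_list_ii <- ranks_ii
      mutations$rank_list <- lapply(seq_len(n_mut), function(i) {
        c(ranks_i[[i]], ranks_ii[[i]])
      })
      mutations$expr_quartile <-
        unname(expression_quartile(stats::setNames(mutations$tpm,
                                                   mutations$mutation_id)))
      profiles[[pt]] <- tumor_profile(sprintf("PT%02d", pt), hla_i, hla_ii,
                                      mutations, clusters)
    }
    np_sum <- vapply(profiles, landscape_sum, numeric(1))
    z <- as.vector(scale(np_sum))
    z[is.na(z)] <- 0
    response <- stats::rbinom(length(profiles), 1L,
                              sigmoid(config$response_effect * z))
    attr(profiles, "response") <- response
    attr(profiles, "truth") <- list(np_sum = np_sum)
    profiles
  })
}
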