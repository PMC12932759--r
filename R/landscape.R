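# Patient-level neoantigen landscape scores: mutation burdens, tumor-centric
# immunogenicity (plain sum, CCF-weighted, clone-structured with dual-MHC
# integration), the CSiN and ioTNL clonality-aware benchmarks, and
# Gini-index tumor-heterogeneity classification.
#
# A tumor profile is a list with fields:
#   patient_id, hla_i, hla_ii  : identifiers / allele vectors
#   mutations                  : data.frame, one row per missense mutation,
#     with (as needed per score) np_immuno_i, np_immuno_ii, phbr_i, ccf,
#     vaf, cluster_id, and a list-column `rank_list` of all pMHC rank
#     percentiles for the mutation
#   clusters                   : data.frame cluster_id, prevalence, n_mutations

#' Construct a tumor profile
#'
#' Light validation wrapper tying a patient's HLA genotype, mutation table
#' and clone-cluster table together. Mutations carrying a `cluster_id` must
#' reference an existing cluster; mutations without one are placed in
#' singleton pseudo-clusters with prevalence equal to their CCF (with a
#' warning) so that clone-structured scores remain defined.
#'
#' @param patient_id Identifier.
#' @param hla_i,hla_ii Character vectors of allele names (non-empty).
#' @param mutations Data.frame of mutation records.
#' @param clusters Optional data.frame with columns `cluster_id`,
#'   `prevalence` and optionally `n_mutations` (recomputed if absent).
#' @return An object of class `tumor_profile`.
#' @export
tumor_profile <- function(patient_id, hla_i, hla_ii, mutations,
                          clusters = NULL) {
  stopifnot(length(hla_i) >= 1L, length(hla_ii) >= 1L,
            is.data.frame(mutations))
  if (is.null(clusters)) {
    clusters <- data.frame(cluster_id = character(0), prevalence = numeric(0),
                           n_mutations = integer(0))
  }
  stopifnot(all(clusters$prevalence >= 0), all(clusters$prevalence <= 1))
  if ("cluster_id" %in% names(mutations)) {
    loose <- !is.na(mutations$cluster_id) &
      !mutations$cluster_id %in% clusters$cluster_id
    if (any(loose)) {
      stop("mutation cluster_id(s) not present in cluster table: ",
           paste(unique(mutations$cluster_id[loose]), collapse = ", "),
           call. = FALSE)
    }
    unassigned <- which(is.na(mutations$cluster_id))
    if (length(unassigned) > 0L) {
      warning(length(unassigned), " mutation(s) lack a cluster; placed in ",
              "singleton pseudo-clusters at their CCF", call. = FALSE)
      for (i in unassigned) {
        cid <- paste0("pseudo_", i)
        mutations$cluster_id[i] <- cid
        clusters <- rbind(clusters,
                          data.frame(cluster_id = cid,
                                     prevalence = mutations$ccf[i],
                                     n_mutations = 1L))
      }
    }
  }
  if (nrow(clusters) > 0L && "cluster_id" %in% names(mutations)) {
    tab <- table(mutations$cluster_id)
    clusters$n_mutations <- as.integer(tab[clusters$cluster_id])
    clusters$n_mutations[is.na(clusters$n_mutations)] <- 0L
  }
  structure(list(patient_id = patient_id, hla_i = hla_i, hla_ii = hla_ii,
                 mutations = mutations, clusters = clusters),
            class = "tumor_profile")
}

#' @export
print.tumor_profile <- function(x, ...) {
  cat("tumor profile", x$patient_id, "-", nrow(x$mutations), "mutations,",
      nrow(x$clusters), "clusters,", length(x$hla_i), "MHC-I /",
      length(x$hla_ii), "MHC-II alleles\n")
  invisible(x)
}

#' Dual-MHC integration of class-wise immunogenicity scores
#'
#' @param np_i,np_ii Scores in [0, 1].
#' @param method `"product"` (default; favors mutations engaging both CD8+
#'   and CD4+ arms), `"sum"` or `"max"`.
#' @return Numeric integrated score.
#' @export
dual_score <- function(np_i, np_ii, method = c("product", "sum", "max")) {
  method <- match.arg(method)
  switch(method,
         product = np_i * np_ii,
         sum = np_i + np_ii,
         max = pmax(np_i, np_ii))
}

#' Mutation burdens: TMB, TNB and immunogenicity burden
#'
#' TMB counts all mutations; TNB those presented on MHC-I (PHBR <= 2); the
#' immunogenicity burden those whose dual recognition score
#' `np_immuno_i * np_immuno_ii` is >= 0.16 (the square of the roughly
#' median per-class score 0.4).
#'
#' @param profile A `tumor_profile` (mutations need `phbr_i`, `np_immuno_i`,
#'   `np_immuno_ii`).
#' @param phbr_threshold MHC-I presentation cutoff (default 2).
#' @param npb_threshold Dual-score cutoff (default 0.16).
#' @return Named numeric vector `c(tmb, tnb, npb)`.
#' @export
mutation_burdens <- function(profile, phbr_threshold = 2,
                             npb_threshold = 0.16) {
  m <- profile$mutations
  if (nrow(m) == 0L) return(c(tmb = 0, tnb = 0, npb = 0))
  c(tmb = nrow(m),
    tnb = sum(m$phbr_i <= phbr_threshold),
    npb = sum(m$np_immuno_i * m$np_immuno_ii >= npb_threshold))
}

#' Landscape score: plain sum
#'
#' `log10(1 + sum of dual scores)` over all scored mutations.
#'
#' @param profile A `tumor_profile`.
#' @param integration Dual-MHC method, see [dual_score()].
#' @return Log-transformed landscape score.
#' @export
landscape_sum <- function(profile, integration = "product") {
  m <- profile$mutations
  if (nrow(m) == 0L) return(0)
  log10(1 + sum(dual_score(m$np_immuno_i, m$np_immuno_ii, integration)))
}

#' Landscape score: CCF-weighted sum
#'
#' `log10(1 + sum of ccf * dual score)`; mutations lacking a CCF are skipped
#' with a warning. Always <= [landscape_sum()] since CCF <= 1.
#'
#' @inheritParams landscape_sum
#' @return Log-transformed landscape score.
#' @export
landscape_ccf <- function(profile, integration = "product") {
  m <- profile$mutations
  if (nrow(m) == 0L) return(0)
  miss <- is.na(m$ccf)
  if (any(miss)) {
    warning(sum(miss), " mutation(s) without CCF skipped", call. = FALSE)
    m <- m[!miss, , drop = FALSE]
  }
  log10(1 + sum(m$ccf * dual_score(m$np_immuno_i, m$np_immuno_ii,
                                   integration)))
}

#' Landscape score: clone-structured
#'
#' Class-wise scores are summed within each clone cluster, integrated across
#' MHC classes per cluster, and averaged over clusters weighted by cluster
#' prevalence: `log10(1 + sum_j prev_j C_j / sum_j prev_j)`.
#'
#' @inheritParams landscape_sum
#' @return Log-transformed landscape score; 0 with a warning when all
#'   prevalences are zero.
#' @export
landscape_clone <- function(profile, integration = "product") {
  m <- profile$mutations
  cl <- profile$clusters
  if (nrow(m) == 0L || nrow(cl) == 0L) return(0)
  stopifnot("cluster_id" %in% names(m))
  if (sum(cl$prevalence) == 0) {
    warning("all cluster prevalences are zero; clone landscape undefined",
            call. = FALSE)
    return(0)
  }
  per_cluster <- vapply(seq_len(nrow(cl)), function(j) {
    rows <- m$cluster_id == cl$cluster_id[j]
    if (!any(rows)) return(0)
    dual_score(sum(m$np_immuno_i[rows]), sum(m$np_immuno_ii[rows]),
               integration)
  }, numeric(1))
  log10(1 + sum(cl$prevalence * per_cluster) / sum(cl$prevalence))
}

#' Cauchy-Schwarz index of neoantigens (CSiN)
#'
#' Clonality-aware benchmark score: mutations are filtered at VAF >= 0.05
#' and capped at the 500 highest-VAF mutations; for each rank-percentile
#' cutoff c the mutations with best pMHC rank q(i) < c contribute the mean
#' of (V_i / mean V)(L_i / mean L), where L_i counts the mutation's pMHC
#' pairs with rank < c and the means run over the included mutations; the
#' score is the mean over cutoffs of the (natural) log of that quantity.
#' Cutoffs with no included mutation are skipped (reducing the divisor)
#' with a warning.
#'
#' @param vaf Numeric vector of variant allele frequencies, one per
#'   mutation.
#' @param rank_lists List (same length) of all pMHC rank percentiles per
#'   mutation (8-11-mer class I and 15-mer class II pairs combined).
#' @param cutoffs Rank-percentile cutoffs (published set by default).
#' @param vaf_min VAF exclusion threshold (default 0.05).
#' @param cap Maximum number of mutations retained, by VAF (default 500).
#' @return CSiN score (0 for a perfectly homogeneous landscape).
#' @export
csin <- function(vaf, rank_lists,
                 cutoffs = c(0.375, 0.5, 0.625, 0.75, 1.25, 1.75, 2),
                 vaf_min = 0.05, cap = 500L) {
  stopifnot(length(vaf) == length(rank_lists))
  keep <- vaf >= vaf_min
  vaf <- vaf[keep]
  rank_lists <- rank_lists[keep]
  if (length(vaf) > cap) {
    ord <- order(vaf, decreasing = TRUE)[seq_len(cap)]
    vaf <- vaf[ord]
    rank_lists <- rank_lists[ord]
  }
  if (length(vaf) == 0L) return(0)
  q <- vapply(rank_lists, min, numeric(1))
  terms <- numeric(0)
  for (cut in cutoffs) {
    inc <- q < cut
    if (!any(inc)) {
      warning("no mutation under cutoff ", cut, "; cutoff skipped",
              call. = FALSE)
      next
    }
    L <- vapply(rank_lists[inc], function(r) sum(r < cut), numeric(1))
    V <- vaf[inc]
    terms <- c(terms, log(mean((V / mean(V)) * (L / mean(L)))))
  }
  if (length(terms) == 0L) return(0)
  mean(terms)
}

#' Immunoediting-optimized tumor neoantigen load (ioTNL)
#'
#' Sums `L_j * CCF_j` over clone clusters whose immune-elimination score
#' `L_j / S_j` falls below the cutoff `e`, where `L_j` is the cluster's
#' neoantigen load and `S_j` its nonsynonymous mutation count.
#'
#' @param clusters Data.frame with columns `neoantigen_load` (L_j),
#'   `n_mutations` (S_j) and `prevalence` (CCF_j).
#' @param e Elimination-score cutoff (default 1.4).
#' @return ioTNL score.
#' @export
iotnl <- function(clusters, e = 1.4) {
  stopifnot(all(c("neoantigen_load", "n_mutations", "prevalence") %in%
                  names(clusters)))
  total <- 0
  for (j in seq_len(nrow(clusters))) {
    S <- clusters$n_mutations[j]
    if (S == 0) {
      warning("cluster with zero mutations skipped", call. = FALSE)
      next
    }
    L <- clusters$neoantigen_load[j]
    if (L / S < e) total <- total + L * clusters$prevalence[j]
  }
  total
}

#' Gini index of a nonnegative vector
#'
#' Mean absolute difference normalized by twice the mean:
#' `sum_ij |x_i - x_j| / (2 n sum_i x_i)`. 0 means perfect equality;
#' the maximum for n values is 1 - 1/n. Scale-invariant.
#'
#' @param values Nonnegative numeric vector (n >= 1).
#' @return Gini index in [0, 1); 0 with a warning when all values are zero.
#' @export
gini <- function(values) {
  stopifnot(length(values) >= 1L, all(values >= 0))
  s <- sum(values)
  if (s == 0) {
    warning("all values are zero; Gini index undefined, returning 0",
            call. = FALSE)
    return(0)
  }
  n <- length(values)
  sum(abs(outer(values, values, `-`))) / (2 * n * s)
}

#' Heterogeneity classification of a cohort
#'
#' Computes per-patient prevalence and size Gini indices over clone
#' clusters and applies the cohort-median quadrant rule: both indices at or
#' below their medians = heterogeneous; both above = homogeneous; the off
#' quadrants = mixed.
#'
#' @param profiles List of `tumor_profile` objects (>= 2).
#' @return Data.frame with columns `patient_id`, `p_gini`, `s_gini`,
#'   `heterogeneity_class`.
#' @export
heterogeneity_class <- function(profiles) {
  if (length(profiles) < 2L) {
    stop("cohort medians need at least 2 patients", call. = FALSE)
  }
  p_gini <- vapply(profiles, function(pr) gini(pr$clusters$prevalence),
                   numeric(1))
  s_gini <- vapply(profiles, function(pr) gini(pr$clusters$n_mutations),
                   numeric(1))
  p_med <- stats::median(p_gini)
  s_med <- stats::median(s_gini)
  cls <- ifelse(p_gini <= p_med & s_gini <= s_med, "heterogeneous",
                ifelse(p_gini > p_med & s_gini > s_med, "homogeneous",
                       "mixed"))
  data.frame(patient_id = vapply(profiles, `[[`, character(1), "patient_id"),
             p_gini = p_gini, s_gini = s_gini,
             heterogeneity_class = cls)
}

#' Clonality summaries of one tumor
#'
#' Fraction of clonal mutations (CCF >= 0.85) and fraction of MHC-I
#' binding mutations (PHBR <= 2), both clipped to [0, 1].
#'
#' @param profile A `tumor_profile` (mutations need `ccf` and `phbr_i`).
#' @param ccf_clonal Clonality threshold (default 0.85).
#' @param phbr_threshold Presentation threshold (default 2).
#' @return Named numeric vector `c(pct_clonal, pct_binding_i)`.
#' @export
clonality_summaries <- function(profile, ccf_clonal = 0.85,
                                phbr_threshold = 2) {
  m <- profile$mutations
  if (nrow(m) == 0L) {
    warning("empty mutation list", call. = FALSE)
    return(c(pct_clonal = 0, pct_binding_i = 0))
  }
  c(pct_clonal = min(1, max(0, mean(m$ccf >= ccf_clonal))),
    pct_binding_i = min(1, max(0, mean(m$phbr_i <= phbr_threshold))))
}

#' Per-cluster neoantigen load from mutation rank lists
#'
#' Counts, per cluster, the pMHC pairs with class-I rank at or below the
#' binder threshold across the cluster's mutations (the load convention
#' used by the presentation-filtered burden).
#'
#' @param profile A `tumor_profile` whose mutations carry `cluster_id` and a
#'   list-column `rank_list_i` of class-I pMHC rank percentiles.
#' @param threshold Class-I binder threshold (default 2).
#' @return The profile's cluster table with an added `neoantigen_load`
#'   column.
#' @export
cluster_neoantigen_load <- function(profile, threshold = 2) {
  m <- profile$mutations
  cl <- profile$clusters
  cl$neoantigen_load <- vapply(cl$cluster_id, function(cid) {
    rows <- which(m$cluster_id == cid)
    sum(vapply(m$rank_list_i[rows], function(r) sum(r <= threshold),
               numeric(1)))
  }, numeric(1))
  cl
}

#' Full landscape summary for one patient
#'
#' Computes every patient-level quantity in one pass: burdens, the three
#' landscape scores, CSiN, ioTNL, Gini indices and clonality summaries.
#'
#' @param profile A `tumor_profile` with fully annotated mutations
#'   (`np_immuno_i/ii`, `phbr_i`, `ccf`, `vaf`, `cluster_id`, `rank_list`
#'   and `rank_list_i` list-columns).
#' @param integration Dual-MHC method for the landscape scores.
#' @return One-row data.frame of landscape quantities.
#' @export
landscape_summary <- function(profile, integration = "product") {
  b <- mutation_burdens(profile)
  cl_load <- cluster_neoantigen_load(profile)
  cs <- clonality_summaries(profile)
  data.frame(
    patient_id = profile$patient_id,
    tmb = b[["tmb"]], tnb = b[["tnb"]], npb = b[["npb"]],
    np_sum = landscape_sum(profile, integration),
    np_ccf = landscape_ccf(profile, integration),
    np_clone = landscape_clone(profile, integration),
    csin = csin(profile$mutations$vaf, profile$mutations$rank_list),
    iotnl = iotnl(cl_load),
    p_gini = gini(profile$clusters$prevalence),
    s_gini = gini(profile$clusters$n_mutations),
    pct_clonal = cs[["pct_clonal"]],
    pct_binding_i = cs[["pct_binding_i"]])
}
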