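# Plain-TSV input/output with a one-line #schema= header, and readers for
# the external table formats the pipeline consumes.

#' Write a table as schema-tagged TSV
#'
#' @param df Data.frame (list columns are not supported).
#' @param path Output path.
#' @param schema Short schema tag written as a `#schema=` comment line.
#' @export
write_tsv <- function(df, path, schema) {
  stopifnot(!any(vapply(df, is.list, logical(1))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#schema=", schema), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a schema-tagged TSV
#'
#' @param path Path written by [write_tsv()] (plain headerless-comment TSV
#'   also works; the schema attribute is then absent).
#' @return Data.frame with attribute `"schema"`.
#' @export
read_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (startsWith(first, "#schema=")) {
    attr(df, "schema") <- sub("^#schema=", "", first)
  }
  df
}

#' Read a clone-cluster table
#'
#' Accepts the package's native columns (`cluster_id`, `prevalence`,
#' `n_mutations`) or external clonal-analysis output columns via
#' `column_map` (e.g. `c(cluster_id = "cluster_id", prevalence =
#' "cellular_prevalence", n_mutations = "size")`).
#'
#' @param path TSV path.
#' @param column_map Named character vector mapping native names to the
#'   file's column names.
#' @return Data.frame with native column names.
#' @export
read_cluster_table <- function(path, column_map = NULL) {
  df <- read_tsv(path)
  if (!is.null(column_map)) {
    for (native in names(column_map)) {
      if (!column_map[[native]] %in% names(df)) {
        stop("mapped column '", column_map[[native]], "' not in ", path,
             call. = FALSE)
      }
      names(df)[names(df) == column_map[[native]]] <- native
    }
  }
  need <- c("cluster_id", "prevalence")
  if (!all(need %in% names(df))) {
    stop("cluster table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Count rows of curated corpus tables
#'
#' Parse-and-count helper over the curated table formats: triplet tables
#' (one row per triplet), labelled epitope tables (one row per pMHC sample)
#' and per-mutation cohort tables with T-cell activity columns.
#'
#' @param path TSV path.
#' @param kind One of `"triplets"`, `"epitopes"`, `"mutations"`.
#' @return Named numeric vector of counts: `n` always; for `mutations`
#'   additionally `cd8_positive`/`cd4_positive` when activity columns are
#'   present.
#' @export
corpus_counts <- function(path, kind = c("triplets", "epitopes",
                                         "mutations")) {
  kind <- match.arg(kind)
  df <- read_tsv(path)
  out <- c(n = nrow(df))
  if (kind == "triplets") {
    stopifnot(all(c("seed", "cross_reactive", "non_cross_reactive")
                  %in% names(df)))
  }
  if (kind == "mutations") {
    if ("cd8_activity" %in% names(df)) {
      out <- c(out, cd8_positive = sum(df$cd8_activity > 0, na.rm = TRUE))
    }
    if ("cd4_activity" %in% names(df)) {
      out <- c(out, cd4_positive = sum(df$cd4_activity > 0, na.rm = TRUE))
    }
  }
  out
}
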