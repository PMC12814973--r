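#' Coerce a data.frame of causal pairs to a truth set
#'
#' @param df data.frame with columns `snp_a`, `snp_b` and optionally
#'   `model_kind`.
#' @return a [truth_set()]-style object.
#' @export
as_truth_set <- function(df) {
  if (!all(c("snp_a", "snp_b") %in% names(df)))
    stop("need columns snp_a and snp_b")
  if (!"model_kind" %in% names(df))
    df$model_kind <- rep(NA_character_, nrow(df))
  out <- data.frame(snp_a = pmin(df$snp_a, df$snp_b),
                    snp_b = pmax(df$snp_a, df$snp_b),
                    model_kind = df$model_kind, stringsAsFactors = FALSE)
  out <- out[!duplicated(pair_key(out$snp_a, out$snp_b)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("truth_set", "data.frame"))
}

#' Benchmark rankings of causal pairs across detection tools
#'
#' Loads the bundled table of per-tool rankings of the simulated causal SNP
#' pairs (each tool reported its top 15 pairs; the table records at which
#' rank each causal pair appeared, `NA` when it did not) and reconstructs,
#' for each tool, a top-15 list with the causal pairs at their reported
#' ranks and synthetic filler pairs at the remaining ranks.
#'
#' @param k list length the rankings refer to (default 15).
#' @return list with `truth` (the 7 causal pairs with their effect models),
#'   `ranks` (the raw table) and `lists` (named list of [top_k()] lists, one
#'   per tool).
#' @export
tool_ranking_fixture <- function(k = 15) {
  path <- system.file("extdata", "tool_rankings.tsv", package = "senkit",
                      mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tools <- setdiff(names(tab), c("snp_a", "snp_b", "effect"))
  truth <- as_truth_set(data.frame(snp_a = tab$snp_a, snp_b = tab$snp_b,
                                   model_kind = tab$effect,
                                   stringsAsFactors = FALSE))
  lists <- lapply(tools, function(tool) {
    ranks <- tab[[tool]]
    a <- character(k); b <- character(k)
    present <- which(!is.na(ranks))
    a[ranks[present]] <- tab$snp_a[present]
    b[ranks[present]] <- tab$snp_b[present]
    fill <- which(a == "")
    a[fill] <- sprintf("fill%s_%02d_a", tool, seq_along(fill))
    b[fill] <- sprintf("fill%s_%02d_b", tool, seq_along(fill))
    t <- pair_score_table(a, b, seq_len(k) / (k + 1), "p_raw",
                          descriptor = protocol_descriptor(tool))
    top_k(t, k)
  })
  names(lists) <- tools
  list(truth = truth, ranks = tab, lists = lists)
}
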