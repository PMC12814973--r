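#' Canonical key for an unordered SNP or gene pair
#'
#' Pairs are stored unordered throughout the package; the canonical form puts
#' the lexicographically smaller identifier first.
#'
#' @param a,b character vectors of identifiers (recycled to common length).
#' @return character vector of keys `"<min>|<max>"`.
#' @keywords internal
pair_key <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Split canonical pair keys back into two identifier columns
#' @param key character vector of `"a|b"` keys.
#' @return data.frame with columns `a` and `b`.
#' @keywords internal
split_pair_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)
  data.frame(a = vapply(parts, `[`, "", 1L),
             b = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

.score_semantics <- c("p_raw", "p_adjusted", "weight", "mean", "run_count")

#' Protocol descriptor
#'
#' Metadata attached to each detection protocol: the tool, its modeling
#' category, whether phenotypes were corrected for population structure,
#' the SNP-to-gene mapping strategy and whether the pair search was
#' exhaustive. Used to annotate clusters of networks.
#'
#' @param tool tool name (e.g. `"allelic_regression"`).
#' @param category modeling-framework label (e.g. `"Statistic"`,
#'   `"Machine learning"`).
#' @param mapping mapping strategy, `"positional"` or `"functional"`.
#' @param corrected logical; phenotype corrected for population structure.
#' @param exhaustive logical; exhaustive pair screening.
#' @param conditional logical; test conditions on main effects.
#' @return object of class `protocol_descriptor` (named list).
#' @export
protocol_descriptor <- function(tool, category = "Statistic",
                                mapping = c("positional", "functional"),
                                corrected = FALSE, exhaustive = TRUE,
                                conditional = FALSE) {
  mapping <- match.arg(mapping)
  stopifnot(is.logical(corrected), is.logical(exhaustive), is.logical(conditional))
  structure(list(tool = as.character(tool), category = as.character(category),
                 mapping = mapping, corrected = corrected,
                 exhaustive = exhaustive, conditional = conditional),
            class = "protocol_descriptor")
}

#' Ranked SNP-pair (or gene-pair) score table
#'
#' The common currency of the package: an unordered-pair-unique table of
#' interaction scores with declared semantics. For p-type semantics lower is
#' better; for `weight` higher is better; for `mean` lower is better (it is
#' converted to a strength 1/(1+mean) at binarization); `run_count` counts
#' detections across perturbed runs.
#'
#' @param a,b identifier vectors for the two pair members.
#' @param score numeric score vector.
#' @param semantics one of `"p_raw"`, `"p_adjusted"`, `"weight"`, `"mean"`,
#'   `"run_count"`.
#' @param descriptor optional [protocol_descriptor()].
#' @return a `pair_score_table`: data.frame with columns `a`, `b`, `score`
#'   (pairs canonicalized so `a < b`), plus attributes `semantics` and
#'   `descriptor`.
#' @export
pair_score_table <- function(a, b, score, semantics, descriptor = NULL) {
  semantics <- match.arg(semantics, .score_semantics)
  a <- as.character(a); b <- as.character(b)
  if (length(a) != length(b) || length(a) != length(score))
    stop("a, b and score must have equal length")
  if (any(a == b)) stop("self pairs (a == b) are not allowed")
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "|")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate unordered pair(s): ", paste(utils::head(dup, 5), collapse = ", "))
  }
  score <- as.numeric(score)
  if (semantics %in% c("p_raw", "p_adjusted") &&
      any(score < 0 | score > 1, na.rm = TRUE))
    stop("p-type scores must lie in [0, 1]")
  if (semantics == "run_count" && any(score < 0 | score != round(score), na.rm = TRUE))
    stop("run_count scores must be non-negative integers")
  out <- data.frame(a = lo, b = hi, score = score, stringsAsFactors = FALSE)
  out <- sort_pair_table(out, semantics)
  structure(out, semantics = semantics, descriptor = descriptor,
            class = c("pair_score_table", "data.frame"))
}

#' @keywords internal
sort_pair_table <- function(df, semantics) {
  decreasing <- semantics %in% c("weight", "run_count")
  o <- order(if (decreasing) -df$score else df$score, df$a, df$b)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Score semantics of a pair table
#' @param x a `pair_score_table` or `gene_pair_table`.
#' @return semantics string.
#' @export
score_semantics <- function(x) attr(x, "semantics")

#' @export
print.pair_score_table <- function(x, ...) {
  cat(sprintf("pair_score_table: %d pairs, semantics = %s\n",
              nrow(x), attr(x, "semantics")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Read a ranked pair table from disk
#'
#' Accepts the PLINK `.epi` dialect (whitespace-separated with a header
#' containing `SNP1`, `SNP2` and `P` — extra columns such as `CHR1` or `STAT`
#' are ignored) or a generic 3-column tab-separated file
#' (`snp_a`, `snp_b`, `score`), with or without a header.
#'
#' @param path file path.
#' @param semantics declared score semantics (see [pair_score_table()]).
#' @param descriptor optional [protocol_descriptor()].
#' @return a [pair_score_table()].
#' @export
read_pair_table <- function(path, semantics, descriptor = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  toks <- strsplit(trimws(first), "[ \t]+")[[1]]
  if (any(toupper(toks) == "SNP1") && any(toupper(toks) == "P")) {
    tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                             check.names = FALSE)
    names(tab) <- toupper(names(tab))
    return(pair_score_table(tab$SNP1, tab$SNP2, tab$P, semantics, descriptor))
  }
  has_header <- suppressWarnings(is.na(as.numeric(toks[3])))
  tab <- utils::read.table(path, header = has_header, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("expected at least 3 columns in ", path)
  pair_score_table(tab[[1]], tab[[2]], tab[[3]], semantics, descriptor)
}

#' Write a pair table in PLINK `.epi`-compatible form
#'
#' Columns `SNP1 SNP2 STAT P` for p-type semantics (STAT left `NA` unless
#' supplied), otherwise a generic 3-column TSV with a header naming the
#' semantics.
#'
#' @param x a [pair_score_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(x, path) {
  sem <- attr(x, "semantics")
  if (sem %in% c("p_raw", "p_adjusted")) {
    out <- data.frame(SNP1 = x$a, SNP2 = x$b, STAT = NA_real_, P = x$score)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    out <- data.frame(snp_a = x$a, snp_b = x$b, score = x$score)
    names(out)[3] <- sem
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
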