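#' Best-k pairs of a score table
#'
#' Takes the best `k` pairs under the table's score semantics (ascending for
#' p-type and `mean`, descending for `weight` and `run_count`), with ties
#' broken lexicographically by the canonical pair ids. If fewer than `k`
#' pairs exist, all are returned.
#'
#' @param t a [pair_score_table()].
#' @param k list length (>= 1).
#' @return a `top_k_list`: data.frame (`a`, `b`, `score`, `rank`) in rank
#'   order, with attributes `k`, `semantics` and `descriptor`.
#' @export
top_k <- function(t, k) {
  if (k < 1) stop("k must be >= 1")
  sem <- attr(t, "semantics")
  df <- sort_pair_table(as.data.frame(t), sem)
  df <- utils::head(df, k)
  df$rank <- seq_len(nrow(df))
  structure(df, k = k, semantics = sem, descriptor = attr(t, "descriptor"),
            class = c("top_k_list", "data.frame"))
}

#' @keywords internal
list_keys <- function(lst) pair_key(lst$a, lst$b)

#' @keywords internal
similarity_matrix <- function(lists, statistic, fun, diag_fun) {
  if (statistic != "recurrent" && length(lists) < 2)
    stop("need at least 2 lists")
  nm <- vapply(seq_along(lists), function(i) {
    d <- attr(lists[[i]], "descriptor")
    if (!is.null(d)) d$tool else sprintf("protocol%02d", i)
  }, "")
  nm <- make.unique(nm)
  M <- length(lists)
  mat <- matrix(0, M, M, dimnames = list(nm, nm))
  for (i in seq_len(M)) {
    mat[i, i] <- diag_fun(lists[[i]])
    if (i < M) for (j in seq((i + 1), M)) {
      v <- fun(lists[[i]], lists[[j]])
      mat[i, j] <- v; mat[j, i] <- v
    }
  }
  structure(mat, statistic = statistic, class = c("protocol_similarity", "matrix"))
}

#' Co-occurrence matrix: shared pairs between top-k lists
#'
#' Entry (i, j) is the number of pairs shared by the top-k lists of
#' protocols i and j; the diagonal holds each list's length.
#'
#' @param lists list of [top_k()] results.
#' @return symmetric matrix with attribute `statistic = "shared_count"`.
#' @export
cooccurrence_matrix <- function(lists) {
  similarity_matrix(lists, "shared_count",
                    function(x, y) length(intersect(list_keys(x), list_keys(y))),
                    function(x) nrow(x))
}

#' Canberra rank-resemblance matrix over top-k lists
#'
#' For each protocol pair, rank vectors are built over the union of the two
#' top-k sets: a pair ranks at its (1-based) list position when present and
#' at k+1 when absent; with `ties = "average"` tied scores within a list
#' share their average position. The distance is the Canberra sum
#' `sum(|x - y| / (x + y))` — disagreements near the top of the lists weigh
#' most. Identical lists are at distance 0.
#'
#' @param lists list of [top_k()] results.
#' @param k the nominal list length (absent rank is k+1); defaults to the
#'   largest `k` attribute among the lists.
#' @param ties `"position"` (default) or `"average"` (average rank within
#'   tied score groups).
#' @return symmetric matrix with attribute `statistic = "canberra_distance"`.
#' @export
canberra_resemblance <- function(lists, k = NULL, ties = c("position", "average")) {
  ties <- match.arg(ties)
  if (is.null(k))
    k <- max(vapply(lists, function(l) attr(l, "k"), numeric(1)))
  ranks_of <- function(l) {
    r <- if (ties == "average") {
      decreasing <- attr(l, "semantics") %in% c("weight", "run_count")
      rank(if (decreasing) -l$score else l$score, ties.method = "average")
    } else l$rank
    stats::setNames(r, list_keys(l))
  }
  dist_fun <- function(x, y) {
    rx <- ranks_of(x); ry <- ranks_of(y)
    u <- union(names(rx), names(ry))
    if (!length(u)) return(0)
    xv <- ifelse(u %in% names(rx), rx[u], k + 1)
    yv <- ifelse(u %in% names(ry), ry[u], k + 1)
    sum(abs(xv - yv) / (xv + yv))
  }
  similarity_matrix(lists, "canberra_distance", dist_fun, function(x) 0)
}

#' Jaccard similarity matrix over top-k sets
#'
#' Entry (i, j) is `|A n B| / |A u B|` over the two top-k pair sets; two
#' empty sets count as identical (similarity 1, with a message).
#'
#' @param lists list of [top_k()] results.
#' @return symmetric matrix with attribute `statistic = "jaccard"`.
#' @export
jaccard_matrix <- function(lists) {
  jac <- function(x, y) {
    A <- list_keys(x); B <- list_keys(y)
    if (!length(A) && !length(B)) {
      message("both lists empty; Jaccard defined as 1")
      return(1)
    }
    length(intersect(A, B)) / length(union(A, B))
  }
  similarity_matrix(lists, "jaccard", jac, function(x) 1)
}

#' Tally how many lists contain each pair
#'
#' Counts, for every pair appearing in at least one top-k list, the number
#' of lists containing it — the "most recurrent pairs" summary. Sorted by
#' descending count, then lexicographically.
#'
#' @param lists list of [top_k()] results (>= 1).
#' @return data.frame (`a`, `b`, `n_lists`).
#' @export
recurrent_pairs <- function(lists) {
  if (length(lists) < 1) stop("need at least 1 list")
  keys <- unlist(lapply(lists, function(l) unique(list_keys(l))))
  tab <- table(keys)
  prs <- split_pair_key(names(tab))
  out <- data.frame(a = prs$a, b = prs$b, n_lists = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_lists, out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a protocol similarity matrix as TSV
#' @param mat a matrix from [cooccurrence_matrix()], [canberra_resemblance()]
#'   or [jaccard_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(mat, path) {
  utils::write.table(cbind(protocol = rownames(mat), as.data.frame(mat)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
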