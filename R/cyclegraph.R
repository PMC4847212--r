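# Per-bin De Bruijn graphs and fixed-length closed-walk detection.
#
# A tandem duplication of length i threads the bin's kmer graph through a
# cycle of exactly i edges; the diagonal of the i-th boolean power of the
# adjacency matrix flags every vertex lying on such a closed walk. Powers
# are taken by exponentiation-by-squaring over the boolean semiring, so no
# entry can overflow and the cost is O(log i) matrix products.

#' Build a De Bruijn graph from a bin's reads
#'
#' Vertices are the `k`-mers observed across the reads (counted per
#' occurrence: a kmer seen twice in one read contributes 2) whose total
#' count lies within `[cov_min, cov_max]`; kmers containing 'N' are
#' excluded. A directed edge joins two surviving kmers whenever they occur
#' adjacently (overlap `k - 1`) in some read.
#'
#' @param sequences character vector of read sequences (or a
#'   `candidate_reads` data.frame).
#' @param k kmer length (`d_kmer`).
#' @param cov_min,cov_max inclusive vertex-coverage window.
#' @return a `debruijn_graph` list: `k`, `vertices` (sorted kmer strings),
#'   `coverage` (named integer), `adjacency` (logical matrix).
#' @export
build_debruijn <- function(sequences, k, cov_min = 1L, cov_max = .Machine$integer.max) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  kmers_by_read <- lapply(sequences, seq_kmers, k = k)
  all_km <- unlist(kmers_by_read, use.names = FALSE)
  empty <- function() structure(
    list(k = as.integer(k), vertices = character(0),
         coverage = integer(0),
         adjacency = matrix(FALSE, 0, 0)),
    class = "debruijn_graph")
  if (!length(all_km)) return(empty())
  cov <- table(all_km)
  cov <- cov[!grepl("N", names(cov), fixed = TRUE)]
  cov <- cov[cov >= cov_min & cov <= cov_max]
  if (!length(cov)) return(empty())
  verts <- sort(names(cov))
  n <- length(verts)
  A <- matrix(FALSE, n, n, dimnames = list(verts, verts))
  for (km in kmers_by_read) {
    if (length(km) < 2) next
    u <- match(km[-length(km)], verts)
    v <- match(km[-1L], verts)
    ok <- !is.na(u) & !is.na(v)
    if (any(ok)) A[cbind(u[ok], v[ok])] <- TRUE
  }
  structure(list(k = as.integer(k), vertices = verts,
                 coverage = stats::setNames(as.integer(cov[verts]), verts),
                 adjacency = A),
            class = "debruijn_graph")
}

# Boolean matrix product.
.bool_mult <- function(x, y) (x %*% y) > 0

# i-th power of a boolean matrix by exponentiation-by-squaring.
bool_mat_pow <- function(A, i) {
  stopifnot(i >= 1)
  acc <- NULL
  base <- A
  while (i > 0) {
    if (i %% 2 == 1)
      acc <- if (is.null(acc)) base else .bool_mult(acc, base)
    i <- i %/% 2
    if (i > 0) base <- .bool_mult(base, base)
  }
  acc
}

#' Vertices on a closed walk of a given length
#'
#' Returns every vertex `v` with a closed walk of exactly `i` edges through
#' `v`, read off the diagonal of the i-th boolean power of the adjacency
#' matrix.
#'
#' @param graph a [build_debruijn()] result.
#' @param i walk length (>= 1); in the pipeline, the bin length.
#' @return character vector of kmers (possibly empty).
#' @export
closed_walk_vertices <- function(graph, i) {
  stopifnot(inherits(graph, "debruijn_graph"), i >= 1)
  if (!length(graph$vertices)) return(character(0))
  P <- bool_mat_pow(graph$adjacency, as.integer(i))
  graph$vertices[diag(P)]
}

#' Retain reads containing at least one cycle kmer
#'
#' @param reads a `candidate_reads` data.frame (one bin's members).
#' @param cycle_kmers character vector from [closed_walk_vertices()].
#' @param k kmer length used to build the graph.
#' @return the filtered data.frame (empty when `cycle_kmers` is empty).
#' @export
filter_reads_by_cycle <- function(reads, cycle_kmers, k) {
  if (!nrow(reads) || !length(cycle_kmers))
    return(reads[integer(0), , drop = FALSE])
  keep <- vapply(reads$sequence,
                 function(s) any(seq_kmers(s, k) %in% cycle_kmers),
                 logical(1), USE.NAMES = FALSE)
  reads[keep, , drop = FALSE]
}
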