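# Greedy overlap-layout-consensus assembly.
#
# Overlap discovery is seed-and-extend: exact shared seeds between oriented
# read pairs propose candidate offsets, each verified by direct base
# comparison over the implied overlap. The layout is built greedily from the
# highest-scoring overlaps with a union-find over read placements (strand +
# offset in a shared component frame); consensus is a per-column majority
# vote. All tie-breaks are total, so assembly is deterministic.

.norm_reads <- function(reads) {
  if (is.data.frame(reads)) {
    ids <- reads$read_id
    seqs <- reads$sequence
  } else {
    seqs <- unname(as.character(reads))
    ids <- names(reads) %||% sprintf("read%04d", seq_along(seqs))
  }
  stopifnot(!anyDuplicated(ids))
  o <- order(ids)
  list(ids = ids[o], seqs = seqs[o])
}

# kmer -> (read index, 0-based offset) table for a set of sequences.
.seed_table <- function(seqs, k) {
  per <- lapply(seqs, seq_kmers, k = k)
  data.table::data.table(
    kmer = unlist(per, use.names = FALSE),
    idx = rep(seq_along(seqs), lengths(per)),
    off = unlist(lapply(lengths(per), seq_len), use.names = FALSE) - 1L)
}

#' Find suffix-prefix overlaps between reads
#'
#' Reports, for each ordered read pair and orientation, every overlap of at
#' least `min_overlap` bases at identity >= `min_identity`. The overhang is
#' the (possibly negative) offset of the oriented second read's start on the
#' first. The output is symmetric: each reported overlap has its mirrored
#' counterpart with the roles swapped.
#'
#' @param reads data.frame with `read_id`/`sequence` columns, or a (named)
#'   character vector.
#' @param min_overlap minimum overlap length (>= 1; the pipeline default
#'   is 15).
#' @param min_identity minimum fraction of matching bases in the overlap
#'   (in `[0.8, 1]`).
#' @param seed_length exact-match seed used to propose candidate offsets
#'   (default `min(12, min_overlap)`); overlaps without an exact seed of
#'   this length are not discovered.
#' @return data.frame with columns `read_a`, `read_b`, `orientation`
#'   ("same"/"rc"), `overhang` (offset of oriented b on a), `length`,
#'   `identity`, sorted by descending score (`length * identity`).
#' @export
find_overlaps <- function(reads, min_overlap = 15L, min_identity = 0.95,
                          seed_length = NULL) {
  stopifnot(min_overlap >= 1, min_identity >= 0.8, min_identity <= 1)
  nr <- .norm_reads(reads)
  ids <- nr$ids; seqs <- nr$seqs
  k <- seed_length %||% min(12L, min_overlap)
  empty <- data.frame(read_a = character(0), read_b = character(0),
                      orientation = character(0), overhang = integer(0),
                      length = integer(0), identity = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(seqs) < 2) return(empty)
  lens <- nchar(seqs)
  rcs <- revcomp(seqs)
  fchars <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  rchars <- lapply(rcs, function(s) strsplit(s, "", fixed = TRUE)[[1]])

  tf <- .seed_table(seqs, k)
  tr <- .seed_table(rcs, k)
  join <- function(tb, orient) {
    m <- merge(tf, tb, by = "kmer", allow.cartesian = TRUE,
               suffixes = c("_a", "_b"))
    m <- m[m$idx_a != m$idx_b, ]
    if (!nrow(m)) return(NULL)
    data.table::data.table(a = m$idx_a, b = m$idx_b, d = m$off_a - m$off_b,
                           orientation = orient)
  }
  cand <- unique(rbind(join(tf, "same"), join(tr, "rc")))
  if (is.null(cand) || !nrow(cand)) return(empty)

  nc <- nrow(cand)
  av <- cand$a; bv <- cand$b; dv <- cand$d; orv <- cand$orientation
  lenv <- integer(nc); idnv <- numeric(nc); ok <- logical(nc)
  for (i in seq_len(nc)) {
    a <- av[i]; b <- bv[i]; d <- dv[i]
    ov_start <- max(0L, d)
    ov_end <- min(lens[a], d + lens[b])
    len <- ov_end - ov_start
    if (len < min_overlap) next
    ob <- if (orv[i] == "same") fchars[[b]] else rchars[[b]]
    idn <- mean(fchars[[a]][(ov_start + 1L):ov_end] ==
                  ob[(ov_start - d + 1L):(ov_end - d)])
    if (idn < min_identity) next
    lenv[i] <- len; idnv[i] <- idn; ok[i] <- TRUE
  }
  if (!any(ok)) return(empty)
  out <- data.frame(read_a = ids[av[ok]], read_b = ids[bv[ok]],
                    orientation = orv[ok], overhang = dv[ok],
                    length = lenv[ok], identity = idnv[ok],
                    stringsAsFactors = FALSE)
  score <- out$length * out$identity
  o <- order(-score, -out$length, out$read_a, out$read_b, out$orientation)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy overlap-layout-consensus assembly
#'
#' Merges reads along the highest-scoring overlaps (score = length x
#' identity; ties broken by longer overlap, then lexicographic read ids)
#' until no overlap joins two distinct components, then calls a per-column
#' majority consensus over each component's layout. Every input read
#' belongs to exactly one contig; reads without usable overlaps become
#' singleton contigs.
#'
#' @inheritParams find_overlaps
#' @return list of `itd_contig` objects: `contig_id`, `sequence`,
#'   `read_ids`, `layout` (data.frame: read_id, strand, offset, length).
#' @export
greedy_assemble <- function(reads, min_overlap = 15L, min_identity = 0.95,
                            seed_length = NULL) {
  nr <- .norm_reads(reads)
  ids <- nr$ids; seqs <- nr$seqs
  n <- length(ids)
  if (!n) return(list())
  ovl <- if (n > 1) find_overlaps(reads, min_overlap, min_identity,
                                  seed_length) else NULL

  comp <- seq_len(n)              # component id per read
  strand <- rep(1L, n)            # +1 forward, -1 reverse in component frame
  offset <- rep(0L, n)
  members <- as.list(seq_len(n))  # component id -> member read indices
  lens <- nchar(seqs)
  idx_of <- stats::setNames(seq_len(n), ids)

  if (!is.null(ovl) && nrow(ovl)) {
    for (i in seq_len(nrow(ovl))) {
      a <- idx_of[[ovl$read_a[i]]]
      b <- idx_of[[ovl$read_b[i]]]
      ca <- comp[a]; cb <- comp[b]
      if (ca == cb) next
      d <- ovl$overhang[i]
      osign <- if (ovl$orientation[i] == "same") 1L else -1L
      if (strand[a] == 1L) {
        s_t <- osign
        o_t <- offset[a] + d
      } else {
        s_t <- -osign
        o_t <- offset[a] + lens[a] - d - lens[b]
      }
      mb <- members[[cb]]
      if (s_t == strand[b]) {
        delta <- o_t - offset[b]
        offset[mb] <- offset[mb] + delta
      } else {
        C <- o_t + offset[b] + lens[b]
        offset[mb] <- C - offset[mb] - lens[mb]
        strand[mb] <- -strand[mb]
      }
      comp[mb] <- ca
      members[[ca]] <- c(members[[ca]], mb)
      members[[cb]] <- integer(0)
    }
  }

  comps <- unique(comp)
  # deterministic contig order: by smallest member read id
  first_id <- vapply(comps, function(cc) min(ids[members[[cc]]]), character(1))
  comps <- comps[order(first_id)]
  out <- vector("list", length(comps))
  for (j in seq_along(comps)) {
    mb <- members[[comps[j]]]
    mb <- mb[order(ids[mb])]
    off <- offset[mb] - min(offset[mb])
    cons <- .consensus(ids[mb], seqs[mb], strand[mb], off, lens[mb])
    out[[j]] <- structure(
      list(contig_id = sprintf("ctg%04d", j), sequence = cons,
           read_ids = ids[mb],
           layout = data.frame(read_id = ids[mb],
                               strand = ifelse(strand[mb] == 1L, "+", "-"),
                               offset = off, length = lens[mb],
                               stringsAsFactors = FALSE)),
      class = "itd_contig")
  }
  out
}

# Majority-vote consensus over a layout; 2-way ties resolve to the base
# carried by the lexicographically smallest covering read id.
.consensus <- function(ids, seqs, strand, offset, lens) {
  W <- max(offset + lens)
  bases <- c("A", "C", "G", "T", "N")
  counts <- matrix(0L, length(bases), W, dimnames = list(bases, NULL))
  oriented <- vector("list", length(ids))
  for (m in seq_along(ids)) {
    s <- if (strand[m] == 1L) seqs[m] else revcomp(seqs[m])
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch[!ch %in% bases] <- "N"
    oriented[[m]] <- ch
    cols <- (offset[m] + 1L):(offset[m] + lens[m])
    ix <- cbind(match(ch, bases), cols)
    counts[ix] <- counts[ix] + 1L
  }
  top <- apply(counts, 2L, max)
  cons <- bases[apply(counts, 2L, which.max)]
  nwin <- colSums(counts == rep(top, each = length(bases)) & counts > 0L)
  ties <- which(nwin > 1L)
  if (length(ties)) {
    ord <- order(ids)
    for (col in ties) {
      winners <- bases[counts[, col] == top[col] & counts[, col] > 0L]
      for (m in ord) {
        p <- col - offset[m]
        if (p >= 1L && p <= lens[m] && oriented[[m]][p] %in% winners) {
          cons[col] <- oriented[[m]][p]
          break
        }
      }
    }
  }
  paste(cons, collapse = "")
}
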