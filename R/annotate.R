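# Contig annotation: duplicated-kmer detection, collapse of one copy,
# local alignment of the collapsed contig to the reference, classification
# against capture targets, allele fraction, optional RNA validation.

#' Leftmost duplicated kmer pair in a contig
#'
#' Finds the leftmost pair of positions `(p1, p2)` (0-based, `p1 < p2`) at
#' which an identical `k`-mer occurs with `r_min <= p2 - p1 <= r_max`.
#' Leftmost means smallest `p1`, ties broken by smallest `p2`.
#'
#' @param contig DNA string (length >= `k`).
#' @param k kmer length (`d_kmer`).
#' @param r_min,r_max inclusive distance range.
#' @return list `p1`, `p2`, `kmer`, or `NULL` when no pair qualifies.
#' @export
find_duplicated_kmer <- function(contig, k, r_min, r_max) {
  stopifnot(nchar(contig) >= k)
  km <- seq_kmers(contig, k)
  dup <- km %in% km[duplicated(km)]
  if (!any(dup)) return(NULL)
  best <- NULL
  for (kmer in unique(km[dup])) {
    pos <- which(km == kmer) - 1L      # 0-based
    for (i in seq_len(length(pos) - 1L)) {
      for (j in (i + 1L):length(pos)) {
        d <- pos[j] - pos[i]
        if (d < r_min || d > r_max) next
        if (is.null(best) || pos[i] < best$p1 ||
            (pos[i] == best$p1 && pos[j] < best$p2))
          best <- list(p1 = pos[i], p2 = pos[j], kmer = kmer)
      }
    }
  }
  best
}

#' Delete the region between a duplicated kmer pair
#'
#' Removes the segment `[p1, p2)` (0-based half-open) from the contig,
#' leaving a single copy of the duplicated sequence.
#'
#' @param contig DNA string.
#' @param p1,p2 positions from [find_duplicated_kmer()] (`p1 < p2`).
#' @return the collapsed contig, of length `nchar(contig) - (p2 - p1)`.
#' @export
collapse_duplication <- function(contig, p1, p2) {
  n <- nchar(contig)
  if (p1 < 0 || p1 >= p2 || p2 > n)
    stop("collapse coordinates out of range")
  paste0(substr(contig, 1L, p1), substr(contig, p2 + 1L, n))
}

# Substitution matrix: match +1, mismatch -2, anything vs N -2.
.sub_matrix <- function() {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-2, 5, 5, dimnames = list(b, b))
  diag(m) <- 1
  m["N", "N"] <- -2
  m
}

# Run one local alignment, return score plus coordinate bookkeeping.
.local_aln <- function(query, subject_chr) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = subject_chr, type = "local",
    substitutionMatrix = .sub_matrix(), gapOpening = 3, gapExtension = 1)
  ap <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  as <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  q0 <- Biostrings::start(Biostrings::pattern(aln)) - 1L   # 0-based
  s0 <- Biostrings::start(Biostrings::subject(aln)) - 1L
  # map query position (0-based) -> reference position (0-based)
  qpos <- q0 - 1L; spos <- s0 - 1L
  qmap <- rep(NA_integer_, nchar(query))
  for (t in seq_along(ap)) {
    if (ap[t] != "-") qpos <- qpos + 1L
    if (as[t] != "-") spos <- spos + 1L
    if (ap[t] != "-" && as[t] != "-") qmap[qpos + 1L] <- spos
  }
  run_max <- function(x) if (any(x)) max(rle(x)$lengths[rle(x)$values]) else 0L
  list(score = Biostrings::score(aln),
       identity = sum(ap == as & ap != "-") / length(ap),
       q_start = q0, q_end = q0 + sum(ap != "-"),
       s_start = s0, s_end = s0 + sum(as != "-"),
       qmap = qmap,
       max_ref_gap = run_max(ap == "-"),
       max_query_gap = run_max(as == "-"))
}

#' Align a collapsed contig to the reference
#'
#' Best local alignment over both strands (match 1, mismatch -2, gap open
#' -3, extend -1). Accepted only when identity >= 0.95 over at least 90\%
#' of the collapsed contig and the best score exceeds the best score
#' attainable elsewhere (computed after masking the best locus, both
#' strands) by at least `min_margin` -- the mapping-specificity
#' requirement.
#'
#' @param collapsed DNA string.
#' @param reference named character vector or `DNAStringSet` of reference
#'   sequences.
#' @param min_identity,min_coverage,min_margin acceptance thresholds.
#' @return list of class `itd_alignment` (`ref_name`, `strand`,
#'   `ref_start`/`ref_end` 0-based half-open, `q_start`/`q_end`, `score`,
#'   `second_score`, `identity`, `coverage`, `qlen`, `qmap` [mapping for
#'   the query as aligned, i.e. reverse-complemented when `strand` is
#'   "-"], `max_ref_gap`, `max_query_gap`), or `NULL` when rejected.
#' @export
align_collapsed <- function(collapsed, reference, min_identity = 0.95,
                            min_coverage = 0.9, min_margin = 10) {
  if (methods::is(reference, "DNAStringSet"))
    reference <- stats::setNames(as.character(reference), names(reference))
  stopifnot(is.character(reference), !is.null(names(reference)))
  queries <- c("+" = collapsed, "-" = revcomp(collapsed))
  alns <- list(); meta <- list()
  for (st in names(queries)) {
    for (ci in seq_along(reference)) {
      alns[[length(alns) + 1L]] <- .local_aln(queries[[st]], reference[[ci]])
      meta[[length(meta) + 1L]] <- list(strand = st, chrom = ci)
    }
  }
  scores <- vapply(alns, `[[`, numeric(1), "score")
  bi <- which.max(scores)
  best <- alns[[bi]]
  strand <- meta[[bi]]$strand
  ci <- meta[[bi]]$chrom
  cover <- (best$q_end - best$q_start) / nchar(collapsed)
  if (best$identity < min_identity || cover < min_coverage) return(NULL)
  # specificity: mask the best locus and realign everywhere, both strands
  masked <- reference
  chr <- masked[[ci]]
  masked[[ci]] <- paste0(substr(chr, 1L, best$s_start),
                         strrep("N", best$s_end - best$s_start),
                         substr(chr, best$s_end + 1L, nchar(chr)))
  second <- max(vapply(masked, function(r)
    max(.local_aln(queries[["+"]], r)$score,
        .local_aln(queries[["-"]], r)$score), numeric(1)))
  if (best$score - second < min_margin) return(NULL)
  structure(list(ref_name = names(reference)[ci], strand = strand,
                 ref_start = best$s_start, ref_end = best$s_end,
                 q_start = best$q_start, q_end = best$q_end,
                 score = best$score, second_score = second,
                 identity = best$identity, coverage = cover,
                 qlen = nchar(collapsed), qmap = best$qmap,
                 max_ref_gap = best$max_ref_gap,
                 max_query_gap = best$max_query_gap),
            class = "itd_alignment")
}

#' Classify an aligned, collapsed contig
#'
#' The duplicated reference segment is the `dup_length` bases starting at
#' the reference position of `p1` (the first duplicated-kmer position,
#' mapped through the alignment). A contiguous alignment (no internal gap
#' over 2 bp on either side) is an insertion-type tandem duplication;
#' otherwise the event is `non_insertion`. Insertion events overlapping a
#' capture-target interval are `coding_ITD` (gene = interval name); with
#' targets supplied but no overlap the event is `off_target`; with no
#' targets it is labelled `intronic` (insertion without capture
#' annotation).
#'
#' @param aln an accepted [align_collapsed()] result.
#' @param p1 0-based position of the retained duplicated-kmer copy in the
#'   collapsed contig.
#' @param dup_length duplication length in bp.
#' @param targets `NULL`, or a data.frame with columns `chrom`, `start`,
#'   `end` (0-based half-open) and `name`.
#' @param k length of the matched kmer anchoring `p1` (default
#'   `dup_length`). The reference locus is anchored on the kmer, which is
#'   always inside the contig even when the duplicated block overhangs a
#'   contig end.
#' @return one-row data.frame: `ref_name`, `start`, `end`, `dup_length`,
#'   `classification`, `gene`; or `NULL` when the anchor falls outside the
#'   aligned span.
#' @export
classify_call <- function(aln, p1, dup_length, targets = NULL,
                          k = dup_length) {
  stopifnot(inherits(aln, "itd_alignment"))
  if (identical(aln$strand, "-")) {
    # rc position of the kmer start; the block extends leftward in reference
    qa <- aln$qlen - p1 - k
    rs <- if (qa >= 0L && qa + 1L <= length(aln$qmap))
      aln$qmap[qa + 1L] else NA_integer_
    if (!is.na(rs)) rs <- rs + as.integer(k) - as.integer(dup_length)
  } else {
    rs <- if (p1 >= 0L && p1 + 1L <= length(aln$qmap))
      aln$qmap[p1 + 1L] else NA_integer_
  }
  if (is.na(rs) || rs < 0L) return(NULL)
  re <- rs + dup_length
  contiguous <- aln$max_ref_gap <= 2L && aln$max_query_gap <= 2L
  cls <- if (!contiguous) "non_insertion" else if (is.null(targets)) {
    "intronic"
  } else {
    hit <- which(targets$chrom == aln$ref_name &
                   targets$start < re & targets$end > rs)
    if (length(hit)) "coding_ITD" else "off_target"
  }
  gene <- if (cls == "coding_ITD") targets$name[hit[1L]] else NA_character_
  data.frame(ref_name = aln$ref_name, start = rs, end = re,
             dup_length = as.integer(dup_length), classification = cls,
             gene = gene, stringsAsFactors = FALSE)
}

#' Left-normalize a tandem-duplication locus
#'
#' A tandem duplication has an ambiguous breakpoint whenever the flanking
#' base matches the corresponding duplicated base; the canonical
#' representation used throughout is the leftmost equivalent interval
#' (shift `[start, end)` left while the base before `start` equals the
#' base before `end`).
#'
#' @param reference_seq DNA string of the reference sequence.
#' @param start,end 0-based half-open duplicated segment.
#' @return integer vector `c(start, end)` of the canonical interval.
#' @export
normalize_dup_locus <- function(reference_seq, start, end) {
  while (start > 0 &&
         substr(reference_seq, start, start) ==
         substr(reference_seq, end, end)) {
    start <- start - 1L
    end <- end - 1L
  }
  c(as.integer(start), as.integer(end))
}

#' Allele fraction of an event
#'
#' @param support_reads junction-supporting read count.
#' @param depth total read depth over the locus (>= `support_reads`).
#' @return `support_reads / depth`; `NA` with a warning when `depth` is 0.
#' @export
allele_fraction <- function(support_reads, depth) {
  stopifnot(support_reads >= 0, depth >= support_reads)
  if (depth == 0) {
    warning("zero depth: allele fraction undefined")
    return(NA_real_)
  }
  support_reads / depth
}

#' Validate an ITD contig against RNA reads
#'
#' An RNA read supports the junction when it aligns to the contig (either
#' strand) with identity strictly greater than `min_identity` over at least
#' 90\% of the read, and its aligned span covers contig positions
#' `junction_offset - 5` through `junction_offset + 5`. The event is
#' evaluable only when at least `min_reads` RNA reads align to the contig
#' at all; it is validated when evaluable and at least one junction-
#' crossing read exists.
#'
#' @param contig_seq contig DNA string.
#' @param junction_offset 0-based contig coordinate of the start of the
#'   second duplicated copy.
#' @param rna_reads character vector of RNA read sequences.
#' @param min_identity identity floor, exclusive (default 0.97).
#' @param min_reads expression floor (default 10 aligned reads).
#' @return list: `n_aligned`, `junction_reads`, `evaluable`, `validated`.
#' @export
rna_validate <- function(contig_seq, junction_offset, rna_reads,
                         min_identity = 0.97, min_reads = 10L) {
  stopifnot(junction_offset >= 0, junction_offset < nchar(contig_seq))
  lo <- max(0L, junction_offset - 5L)
  hi <- min(nchar(contig_seq) - 1L, junction_offset + 5L)
  n_aligned <- 0L; junction <- 0L
  for (r in rna_reads) {
    cand <- list(.local_aln(r, contig_seq), .local_aln(revcomp(r), contig_seq))
    a <- cand[[which.max(vapply(cand, `[[`, numeric(1), "score"))]]
    cover <- (a$q_end - a$q_start) / nchar(r)
    if (a$identity > min_identity && cover >= 0.9) {
      n_aligned <- n_aligned + 1L
      if (a$s_start <= lo && a$s_end >= hi + 1L)
        junction <- junction + 1L
    }
  }
  evaluable <- n_aligned >= min_reads
  list(n_aligned = n_aligned, junction_reads = junction,
       evaluable = evaluable, validated = evaluable && junction >= 1L)
}

#' Merge duplicate calls
#'
#' Calls sharing `(ref_name, start, dup_length)` (e.g. the same event
#' recovered from several bins) are merged keeping the row with maximum
#' support; output is sorted by locus. Calls with distinct lengths at one
#' locus are all retained (bi-allelic events).
#'
#' @param calls data.frame of calls.
#' @return merged, sorted data.frame.
#' @export
merge_calls <- function(calls) {
  if (!nrow(calls)) return(calls)
  key <- paste(calls$ref_name, calls$start, calls$dup_length, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(calls)), key), function(ix) {
    ix[order(-calls$support_reads[ix], calls$contig_id[ix])][1L]
  }), use.names = FALSE)
  out <- calls[keep, , drop = FALSE]
  out <- out[order(out$ref_name, out$start, out$dup_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write calls as BED6+4
#'
#' Columns: chrom, start, end, name (`gene|dup_length`), score
#' (support_reads), strand ("."), allele_fraction, classification,
#' contig_id, junction_offset. Parameter echo lines are written as `#`
#' comments.
#'
#' @param calls data.frame of calls.
#' @param path output file.
#' @param params optional [itd_params()] echoed into the header.
#' @return invisibly, `path`.
#' @export
write_itd_bed <- function(calls, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params)) {
    flat <- unlist(params)
    writeLines(paste0("# ", names(flat), "=", flat), con)
  }
  if (nrow(calls)) {
    nm <- paste0(ifelse(is.na(calls$gene), ".", calls$gene), "|",
                 calls$dup_length)
    df <- data.frame(calls$ref_name, calls$start, calls$end, nm,
                     calls$support_reads, ".",
                     calls$allele_fraction, calls$classification,
                     calls$contig_id, calls$junction_offset)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read calls written by [write_itd_bed()]
#'
#' @param path BED file path.
#' @return data.frame of calls (lossless round trip of the written fields).
#' @export
read_itd_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  cols <- c("ref_name", "start", "end", "name", "support_reads", "strand",
            "allele_fraction", "classification", "contig_id",
            "junction_offset")
  if (!length(lines)) {
    df <- data.frame(ref_name = character(0), start = integer(0),
                     end = integer(0), name = character(0),
                     support_reads = integer(0), strand = character(0),
                     allele_fraction = numeric(0),
                     classification = character(0), contig_id = character(0),
                     junction_offset = integer(0))
  } else {
    df <- utils::read.table(text = lines, sep = "\t",
                            col.names = cols, stringsAsFactors = FALSE)
  }
  parts <- strsplit(df$name, "|", fixed = TRUE)
  df$gene <- vapply(parts, function(p) if (length(p) && p[1] != ".")
    p[1] else NA_character_, character(1))
  df$dup_length <- vapply(parts, function(p) as.integer(p[2]), integer(1))
  df$name <- NULL
  df
}
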