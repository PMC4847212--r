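# Candidate-read extraction from alignment files.
#
# SAM is 1-based at the file boundary; every coordinate exposed by this
# package is 0-based half-open. Conversion happens only here.

# Accept .sam or .bam; return the path to a sorted, indexed BAM.
ensure_bam <- function(file) {
  if (!file.exists(file)) stop("alignment file not found: ", file)
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- sub("\\.sam$", "", file, ignore.case = TRUE)
    bam <- paste0(dest, ".bam")
    if (!file.exists(bam) ||
        file.mtime(bam) < file.mtime(file)) {
      bam <- Rsamtools::asBam(file, destination = dest, overwrite = TRUE,
                              indexDestination = TRUE)
    }
    bam
  } else {
    if (!file.exists(paste0(file, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", file)))
      Rsamtools::indexBam(file)
    file
  }
}

.cigar_ok <- function(cig) grepl("^([0-9]+[MIDNSHP=X])+$", cig)

#' Extract candidate reads from an alignment file
#'
#' Candidates are (a) reads with the unmapped flag set and (b) mapped reads
#' whose CIGAR carries a leading or trailing soft-clip of at least
#' `min_clip` bases; a read with qualifying clips on both sides yields two
#' entries (one per side). Secondary, supplementary and duplicate-marked
#' records are skipped, as are reads shorter than 20 bases or with a missing
#' sequence.
#'
#' @param file path to a SAM or BAM file.
#' @param min_clip minimum soft-clip length to extract (default 4).
#' @return a data.frame of class `candidate_reads` with columns `read_id`,
#'   `qname`, `sequence`, `origin` ("unmapped"/"softclip"), `clip_segment`,
#'   `clip_side` ("head"/"tail" or NA), `ref_name`, `pos` (0-based mapped
#'   position of the aligned portion, soft-clipped reads only).
#' @export
extract_candidates <- function(file, min_clip = 4L) {
  stopifnot(min_clip >= 1)
  bam <- ensure_bam(file)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- res$flag
  keep <- bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L &
    bitwAnd(flag, 1024L) == 0L
  qname <- res$qname[keep]
  flag <- flag[keep]
  rname <- as.character(res$rname)[keep]
  pos <- res$pos[keep]
  cigar <- res$cigar[keep]
  seqs <- as.character(res$seq)[keep]

  empty <- function() data.frame(
    read_id = character(0), qname = character(0), sequence = character(0),
    origin = character(0), clip_segment = character(0),
    clip_side = character(0), ref_name = character(0), pos = integer(0),
    stringsAsFactors = FALSE)

  rows <- list()
  unm <- bitwAnd(flag, 4L) != 0L
  bad_seq <- is.na(seqs) | seqs == "" | seqs == "*"
  if (any(unm & bad_seq))
    warning(sum(unm & bad_seq), " unmapped record(s) with missing sequence skipped")
  short <- !bad_seq & nchar(seqs) < 20L
  if (any(short))
    warning(sum(short), " record(s) shorter than 20 bases skipped")
  use_unm <- unm & !bad_seq & !short
  if (any(use_unm)) {
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = qname[use_unm], qname = qname[use_unm],
      sequence = seqs[use_unm], origin = "unmapped",
      clip_segment = NA_character_, clip_side = NA_character_,
      ref_name = NA_character_, pos = NA_integer_, stringsAsFactors = FALSE)
  }

  mp <- !unm & !bad_seq & !short
  if (any(mp)) {
    cig <- cigar[mp]
    bad_cig <- is.na(cig) | cig == "*" | !.cigar_ok(cig)
    if (any(bad_cig))
      warning(sum(bad_cig), " mapped record(s) with unusable CIGAR skipped")
    idx <- which(mp)[!bad_cig]
    cig <- cigar[idx]
    head_clip <- suppressWarnings(
      as.integer(sub("^([0-9]+)S.*$", "\\1", cig)))
    head_clip[!grepl("^[0-9]+S", cig)] <- 0L
    tail_clip <- suppressWarnings(
      as.integer(sub("^.*?([0-9]+)S$", "\\1", cig, perl = TRUE)))
    tail_clip[!grepl("[0-9]+S$", cig)] <- 0L
    # a pure-clip CIGAR like "75S" would match both; treat as head only
    both_same <- grepl("^[0-9]+S$", cig)
    tail_clip[both_same] <- 0L
    h <- head_clip >= min_clip
    if (any(h)) {
      i <- idx[h]
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = paste0(qname[i], "/Shead"), qname = qname[i],
        sequence = seqs[i], origin = "softclip",
        clip_segment = substr(seqs[i], 1L, head_clip[h]),
        clip_side = "head", ref_name = rname[i], pos = pos[i] - 1L,
        stringsAsFactors = FALSE)
    }
    tl <- tail_clip >= min_clip
    if (any(tl)) {
      i <- idx[tl]
      n <- nchar(seqs[i])
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = paste0(qname[i], "/Stail"), qname = qname[i],
        sequence = seqs[i], origin = "softclip",
        clip_segment = substr(seqs[i], n - tail_clip[tl] + 1L, n),
        clip_side = "tail", ref_name = rname[i], pos = pos[i] - 1L,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty()
  out <- out[order(out$read_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_reads", "data.frame")
  out
}

#' Depth of primary alignments over a 1-bp locus
#'
#' Counts primary, non-duplicate, mapped alignments overlapping the locus;
#' used as (part of) the allele-fraction denominator.
#'
#' @param file path to a SAM or BAM file.
#' @param ref_name reference sequence name.
#' @param pos 0-based reference position.
#' @return integer count.
#' @export
hard_filtered_depth <- function(file, ref_name, pos) {
  bam <- ensure_bam(file)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!ref_name %in% names(hdr))
    stop("unknown reference sequence: ", ref_name)
  if (pos < 0 || pos >= hdr[[ref_name]])
    stop("locus off the reference: ", pos)
  which <- GenomicRanges::GRanges(ref_name, IRanges::IRanges(pos + 1L, pos + 1L))
  p <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE),
    which = which)
  as.integer(Rsamtools::countBam(bam, param = p)$records)
}
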