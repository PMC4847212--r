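# Synthetic data: references with implanted tandem duplications and
# deterministic exome-like read sets with truth records.
#
# The simulator stands in for a real aligner with a deterministic surrogate:
# a read whose span reaches >= 4 bp past a junction of the duplicated copy on
# both sides is emitted as unmapped (BWA's typical failure mode for
# junction-spanning reads); a read overhanging a junction by 1-3 bp is
# emitted mapped with the overhang soft-clipped; all other reads are mapped.

#' Truth record for one implanted tandem duplication
#'
#' @param ref_name reference (chromosome) name.
#' @param start 0-based reference offset of the first duplicated base.
#' @param dup_length duplication length in bp (>= 1).
#' @param allele_fraction mixture weight of the duplication-carrying allele,
#'   in `[0, 1]`.
#' @return a `truth_itd` list.
#' @export
truth_itd <- function(ref_name, start, dup_length, allele_fraction) {
  stopifnot(start >= 0, dup_length >= 1,
            allele_fraction >= 0, allele_fraction <= 1)
  structure(list(ref_name = ref_name, start = as.integer(start),
                 dup_length = as.integer(dup_length),
                 allele_fraction = allele_fraction),
            class = "truth_itd")
}

#' Simulation configuration
#'
#' @param ref_length reference length in bp.
#' @param read_length read length in bp (>= 20).
#' @param coverage target mean fold-coverage over the reference (> 0).
#' @param error_rate per-base substitution probability, in `[0, 0.1)`.
#' @param seed integer RNG seed; fixed seed gives byte-identical output.
#' @param itds list of [truth_itd()] records (summed allele fractions <= 1).
#' @param ref_name reference sequence name.
#' @return a `sim_config` list.
#' @export
sim_config <- function(ref_length, read_length = 75L, coverage = 100,
                       error_rate = 0, seed = 1L, itds = list(),
                       ref_name = "chrS") {
  stopifnot(ref_length >= 1, read_length >= 20, coverage > 0,
            error_rate >= 0, error_rate < 0.1)
  if (length(itds)) {
    stopifnot(all(vapply(itds, inherits, logical(1), "truth_itd")))
    af <- sum(vapply(itds, `[[`, numeric(1), "allele_fraction"))
    stopifnot(af <= 1)
    for (t in itds)
      stopifnot(t$start + t$dup_length <= ref_length)
  }
  structure(list(ref_length = as.integer(ref_length),
                 read_length = as.integer(read_length),
                 coverage = coverage, error_rate = error_rate,
                 seed = as.integer(seed), itds = itds, ref_name = ref_name),
            class = "sim_config")
}

#' Generate a random reference sequence
#'
#' Uniform over A/C/G/T, with homopolymer runs of 15 or more regenerated so
#' that simulated reads are never lost to the homopolymer filter by accident.
#'
#' @param length reference length in bp (>= 1).
#' @param seed integer RNG seed.
#' @return a single DNA string of exactly `length` bases.
#' @export
make_reference <- function(length, seed = 1L) {
  if (length < 1) stop("reference length must be >= 1")
  with_seed(seed, {
    x <- sample(DNA_BASES, length, replace = TRUE)
    repeat {
      r <- rle(x)
      bad <- which(r$lengths >= 15L)
      if (!length(bad)) break
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (b in bad) {
        idx <- seq.int(starts[b], ends[b])
        x[idx] <- sample(DNA_BASES, length(idx), replace = TRUE)
      }
    }
    paste(x, collapse = "")
  })
}

#' Implant a tandem duplication into a reference
#'
#' The segment `[start, start + dup_length)` (0-based) is duplicated in
#' tandem immediately after itself.
#'
#' @param reference DNA string.
#' @param start 0-based offset of the first duplicated base.
#' @param dup_length duplication length in bp (0 is the identity).
#' @return the duplication-carrying allele, of length
#'   `nchar(reference) + dup_length`.
#' @export
implant_itd <- function(reference, start, dup_length) {
  n <- nchar(reference)
  if (start < 0 || dup_length < 0 || start + dup_length > n)
    stop("duplication coordinates out of range")
  if (dup_length == 0) return(reference)
  paste0(substr(reference, 1L, start + dup_length),
         substr(reference, start + 1L, n))
}

# Map an allele coordinate (0-based) to its reference coordinate for an
# allele carrying one duplication of `dup` bp whose second copy starts at
# allele offset `j1` (= start + dup).
.allele2ref <- function(a, j1, dup) ifelse(a < j1, a, a - dup)

#' Simulate single-end reads over a reference with implanted duplications
#'
#' Reads are sampled uniformly (position and strand) from a mixture of the
#' reference allele and one mutant allele per duplication, with per-read
#' allele probabilities equal to the configured allele fractions.
#' Substitution errors are applied at `error_rate`. Mapping status follows
#' the deterministic aligner surrogate described above.
#'
#' @param cfg a [sim_config()].
#' @param reference optional DNA string; generated from `cfg` when `NULL`.
#' @return a list with elements `reference` (DNA string), `reads`
#'   (data.frame: read_id, seq [as sequenced], strand, status
#'   \{mapped, unmapped, softclip\}, ref_pos [0-based mapped start or NA],
#'   cigar, allele [0 = reference, else ITD index], allele_start
#'   [0-based sampled start on the source allele]) and `truth` (data.frame:
#'   chrom, start, end, name, score, allele_fraction).
#' @export
simulate_reads <- function(cfg, reference = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(reference))
    reference <- make_reference(cfg$ref_length, seed = cfg$seed + 104729L)
  stopifnot(nchar(reference) == cfg$ref_length)
  R <- cfg$read_length
  alleles <- list(reference)
  junctions <- list(integer(0))
  for (t in cfg$itds) {
    alleles[[length(alleles) + 1L]] <- implant_itd(reference, t$start, t$dup_length)
    junctions[[length(junctions) + 1L]] <-
      c(t$start + t$dup_length, t$start + 2L * t$dup_length)
  }
  afs <- vapply(cfg$itds, `[[`, numeric(1), "allele_fraction")
  pr <- c(1 - sum(afs), afs)
  n_reads <- as.integer(round(cfg$coverage * cfg$ref_length / R))

  reads <- with_seed(cfg$seed, {
    allele_idx <- sample.int(length(alleles), n_reads, replace = TRUE, prob = pr)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqv <- character(n_reads); statusv <- character(n_reads)
    posv <- rep(NA_integer_, n_reads); cigv <- character(n_reads)
    startv <- integer(n_reads)
    for (i in seq_len(n_reads)) {
      ai <- allele_idx[i]
      A <- alleles[[ai]]
      la <- nchar(A)
      s <- sample.int(la - R + 1L, 1L) - 1L          # 0-based start on allele
      fwd <- substr(A, s + 1L, s + R)
      J <- junctions[[ai]]
      ov <- J[J > s & J < s + R]                      # junctions inside span
      side_min <- if (length(ov)) pmin(ov - s, s + R - ov) else integer(0)
      status <- "mapped"; cigar <- paste0(R, "M"); ref_pos <- NA_integer_
      if (length(ov) && any(side_min >= 4L)) {
        status <- "unmapped"; cigar <- "*"
      } else if (length(ov)) {
        status <- "softclip"
        j <- ov[which.min(side_min)]
        t0 <- cfg$itds[[ai - 1L]]
        j1 <- t0$start + t0$dup_length
        if (j - s <= 3L) {                            # clip at head
          clip <- j - s
          ref_pos <- .allele2ref(j, j1, t0$dup_length)
          cigar <- paste0(clip, "S", R - clip, "M")
        } else {                                      # clip at tail
          clip <- s + R - j
          ref_pos <- .allele2ref(s, j1, t0$dup_length)
          cigar <- paste0(R - clip, "M", clip, "S")
        }
      } else {
        ref_pos <- if (ai == 1L) s else {
          t0 <- cfg$itds[[ai - 1L]]
          .allele2ref(s, t0$start + t0$dup_length, t0$dup_length)
        }
      }
      if (cfg$error_rate > 0) {
        hit <- which(stats::runif(R) < cfg$error_rate)
        if (length(hit)) {
          ch <- strsplit(fwd, "", fixed = TRUE)[[1]]
          for (p in hit)
            ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
          fwd <- paste(ch, collapse = "")
        }
      }
      seqv[i] <- fwd; statusv[i] <- status; posv[i] <- ref_pos
      cigv[i] <- cigar; startv[i] <- s
    }
    seqv <- ifelse(strand == "-", revcomp(seqv), seqv)
    data.frame(read_id = sprintf("r%06d", seq_len(n_reads)), seq = seqv,
               strand = strand, status = statusv, ref_pos = posv,
               cigar = cigv, allele = allele_idx - 1L, allele_start = startv,
               stringsAsFactors = FALSE)
  })

  truth <- if (length(cfg$itds)) {
    data.frame(chrom = cfg$ref_name,
               start = vapply(cfg$itds, `[[`, integer(1), "start"),
               end = vapply(cfg$itds, function(t) t$start + t$dup_length, integer(1)),
               name = "ITD",
               score = vapply(cfg$itds, `[[`, integer(1), "dup_length"),
               allele_fraction = afs,
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0), score = integer(0),
               allele_fraction = numeric(0))
  }
  list(reference = reference, reads = reads, truth = truth)
}

#' Write simulation output to FASTA/FASTQ/SAM/BED
#'
#' @param sim result of [simulate_reads()].
#' @param cfg the [sim_config()] used.
#' @param prefix file path prefix; writes `<prefix>.fa`, `<prefix>.fastq`,
#'   `<prefix>.sam`, `<prefix>.truth.bed`.
#' @return invisibly, a named list of the file paths written.
#' @export
write_sim <- function(sim, cfg, prefix) {
  fa <- paste0(prefix, ".fa")
  ref <- Biostrings::DNAStringSet(sim$reference)
  names(ref) <- cfg$ref_name
  Biostrings::writeXStringSet(ref, fa)
  fq <- paste0(prefix, ".fastq")
  writeLines(as.vector(rbind(paste0("@", sim$reads$read_id), sim$reads$seq,
                             "+", strrep("I", nchar(sim$reads$seq)))), fq)
  sam <- paste0(prefix, ".sam")
  write_sim_sam(sim$reads, cfg$ref_name, nchar(sim$reference), sam)
  bed <- paste0(prefix, ".truth.bed")
  utils::write.table(sim$truth, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(list(fasta = fa, fastq = fq, sam = sam, truth = bed))
}

# SAM writer for the simulator. Mapped reads are written in reference-forward
# orientation (flag 0x10 for minus strand); unmapped reads keep the
# as-sequenced bases with flag 0x4. Coordinate-sorted, unmapped records last.
write_sim_sam <- function(reads, ref_name, ref_length, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", ref_name, "\tLN:", ref_length))
  mapped <- reads[reads$status != "unmapped", , drop = FALSE]
  unm <- reads[reads$status == "unmapped", , drop = FALSE]
  lines <- character(0)
  if (nrow(mapped)) {
    mapped <- mapped[order(mapped$ref_pos, mapped$read_id), , drop = FALSE]
    flag <- ifelse(mapped$strand == "-", 16L, 0L)
    seq_fwd <- ifelse(mapped$strand == "-", revcomp(mapped$seq), mapped$seq)
    lines <- c(lines, paste(mapped$read_id, flag, ref_name, mapped$ref_pos + 1L,
                            60L, mapped$cigar, "*", 0L, 0L, seq_fwd,
                            strrep("I", nchar(seq_fwd)), sep = "\t"))
  }
  if (nrow(unm)) {
    unm <- unm[order(unm$read_id), , drop = FALSE]
    lines <- c(lines, paste(unm$read_id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                            unm$seq, strrep("I", nchar(unm$seq)), sep = "\t"))
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
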