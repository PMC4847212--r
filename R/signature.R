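# Read-level filters, kmer frequency-spectrum analysis and binning.
#
# A read harbors a tandem-duplication signature when some p_kmer-length
# substring occurs twice; the distance between consecutive occurrences of a
# duplicated kmer equals the duplication length, so reads are clustered into
# bins keyed by that distance.

#' Pipeline parameters
#'
#' @param p_kmer partial-duplication kmer length (default 10). The pipeline
#'   is blind to partial duplications shorter than `p_kmer`.
#' @param d_kmer De Bruijn graph kmer length; must be >= `p_kmer`
#'   (default `p_kmer`).
#' @param r_min,r_max inclusive range of duplication lengths for which bins
#'   are created. `r_max` is additionally capped at read length - `p_kmer`
#'   at run time. `r_min` must be >= `p_kmer` (a duplication shorter than
#'   `p_kmer` cannot repeat a `p_kmer`-mer).
#' @param cov_cutoff_min,cov_cutoff_max kmer coverage window for De Bruijn
#'   graph vertices. Defaults 2 and 10000: drop singleton (likely error)
#'   kmers, keep everything else.
#' @param max_n maximum number of 'N' bases tolerated per read (default 50).
#' @param max_homopolymer longest retained single-base run (default 14).
#' @param min_overlap,min_identity overlap-layout-consensus assembly
#'   thresholds (defaults 15 bp and 0.95).
#' @param min_clip minimum soft-clip length for candidate extraction.
#' @param light skip the De Bruijn cycle filter and assemble each bin
#'   directly (lower memory, more reads into assembly).
#' @param preset optional named preset; `"flt3"` sets
#'   `p_kmer = d_kmer = 15`, `cov_cutoff_min = 30`, `cov_cutoff_max = 200`,
#'   `r_min = 15`, `r_max = 85`.
#' @return a validated `itd_params` list.
#' @export
itd_params <- function(p_kmer = 10L, d_kmer = p_kmer, r_min = 15L,
                       r_max = 61L, cov_cutoff_min = 2L,
                       cov_cutoff_max = 10000L, max_n = 50L,
                       max_homopolymer = 14L, min_overlap = 15L,
                       min_identity = 0.95, min_clip = 4L, light = FALSE,
                       preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "flt3")
    if (preset == "flt3") {
      p_kmer <- 15L; d_kmer <- 15L; cov_cutoff_min <- 30L
      cov_cutoff_max <- 200L; r_min <- 15L; r_max <- 85L
    }
  }
  p <- list(p_kmer = as.integer(p_kmer), d_kmer = as.integer(d_kmer),
            r_min = as.integer(r_min), r_max = as.integer(r_max),
            cov_cutoff_min = as.integer(cov_cutoff_min),
            cov_cutoff_max = as.integer(cov_cutoff_max),
            max_n = as.integer(max_n),
            max_homopolymer = as.integer(max_homopolymer),
            min_overlap = as.integer(min_overlap),
            min_identity = min_identity, min_clip = as.integer(min_clip),
            light = isTRUE(light))
  stopifnot(p$p_kmer >= 1, p$d_kmer >= p$p_kmer, p$r_min >= p$p_kmer,
            p$r_max >= p$r_min, p$cov_cutoff_min <= p$cov_cutoff_max,
            p$cov_cutoff_min >= 0, p$max_n >= 0, p$max_homopolymer >= 1,
            p$min_overlap >= 10, p$min_identity >= 0.8,
            p$min_identity <= 1, p$min_clip >= 1)
  class(p) <- "itd_params"
  p
}

#' Count occurrences of a base in a string
#'
#' @param s a string.
#' @param x a single character.
#' @return integer count.
#' @export
count_base <- function(s, x) {
  nchar(s) - nchar(gsub(x, "", s, fixed = TRUE))
}

#' Filter reads by N content
#'
#' Retains reads with at most `max_n` 'N' bases.
#'
#' @param reads a `candidate_reads` data.frame (or any data.frame with a
#'   `sequence` column).
#' @param max_n maximum tolerated N count.
#' @return the filtered data.frame.
#' @export
filter_n <- function(reads, max_n = 50L) {
  if (!nrow(reads)) return(reads)
  nn <- vapply(reads$sequence, count_base, integer(1), x = "N",
               USE.NAMES = FALSE)
  reads[nn <= max_n, , drop = FALSE]
}

#' Filter reads by homopolymer run length
#'
#' Retains reads whose longest single-base run is at most `max_run`.
#'
#' @param reads a `candidate_reads` data.frame.
#' @param max_run longest retained run (default 14; runs of 15+ are dropped).
#' @return the filtered data.frame.
#' @export
filter_homopolymer <- function(reads, max_run = 14L) {
  if (!nrow(reads)) return(reads)
  runs <- vapply(reads$sequence, max_homopolymer_run, integer(1),
                 USE.NAMES = FALSE)
  reads[runs <= max_run, , drop = FALSE]
}

#' Repeat distances of duplicated kmers in a read
#'
#' Returns the set of distances between consecutive occurrences of every
#' kmer occurring at least twice in `S`. The set is empty exactly when all
#' kmers of `S` are distinct, i.e. when the kmer spectrum has full size
#' `|S| - k + 1`.
#'
#' @param S DNA string.
#' @param k kmer length (>= 1, <= `nchar(S)`).
#' @return sorted integer vector of distances (possibly empty).
#' @export
repeat_distances <- function(S, k) {
  if (k < 1) stop("k must be >= 1")
  if (nchar(S) < k) stop("string shorter than k")
  km <- seq_kmers(S, k)
  dup <- km %in% km[duplicated(km)]
  if (!any(dup)) return(integer(0))
  pos <- which(dup)
  d <- unlist(lapply(split(pos, km[pos]), function(p) diff(sort(p))),
              use.names = FALSE)
  sort(unique(as.integer(d)))
}

# Distances between consecutive occurrences of a clip segment within the
# full read (soft-clipped candidates: the clip itself is the query kmer).
clip_repeat_distances <- function(sequence, clip) {
  if (!nchar(clip) || nchar(clip) > nchar(sequence)) return(integer(0))
  m <- Biostrings::matchPattern(clip, Biostrings::DNAString(sequence))
  p <- Biostrings::start(m)
  if (length(p) < 2) return(integer(0))
  sort(unique(as.integer(diff(sort(p)))))
}

#' Annotate reads with repeat signatures and cluster them into bins
#'
#' Unmapped candidates are scanned for duplicated `p_kmer`-mers; soft-clipped
#' candidates are scanned for re-occurrences of the clip segment only (the
#' clip length plays the role of `p_kmer` for that read). A read is placed
#' in bin `i` for every repeat distance `i` within `[r_min, r_max]`; reads
#' with multiple distances go to all matching bins, reads with none are
#' dropped.
#'
#' @param reads a `candidate_reads` data.frame (post filtering).
#' @param params an [itd_params()] object.
#' @return named list (bin length -> data.frame of member reads), class
#'   `itd_bins`.
#' @export
bin_reads <- function(reads, params) {
  stopifnot(inherits(params, "itd_params"))
  bins <- list()
  if (nrow(reads)) {
    dists <- vector("list", nrow(reads))
    for (i in seq_len(nrow(reads))) {
      d <- if (identical(reads$origin[i], "softclip")) {
        clip_repeat_distances(reads$sequence[i], reads$clip_segment[i])
      } else if (nchar(reads$sequence[i]) >= params$p_kmer) {
        repeat_distances(reads$sequence[i], params$p_kmer)
      } else integer(0)
      dists[[i]] <- d[d >= params$r_min & d <= params$r_max]
    }
    lens <- lengths(dists)
    if (any(lens > 0)) {
      long <- data.frame(row = rep(seq_len(nrow(reads)), lens),
                         bin = unlist(dists))
      for (b in sort(unique(long$bin))) {
        bins[[as.character(b)]] <- reads[long$row[long$bin == b], ,
                                         drop = FALSE]
      }
    }
  }
  structure(bins, class = "itd_bins")
}
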