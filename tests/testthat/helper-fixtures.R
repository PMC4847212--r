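# Shared fixtures: hand-built SAM files, simulation shortcuts, and the
# independent oracles used to freeze expected values.

sam_file <- function(records, ref_name = "chrT", ref_len = 1000L) {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               paste0("@SQ\tSN:", ref_name, "\tLN:", ref_len),
               records), path)
  path
}

sam_record <- function(qname, flag, rname, pos, cigar, seq,
                       mapq = 60L) {
  qual <- if (identical(seq, "*")) "*" else strrep("I", nchar(seq))
  paste(qname, flag, rname, pos, mapq, cigar, "*", 0L, 0L, seq, qual,
        sep = "\t")
}

rand_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else itdscan:::with_seed(seed, draw())
}

# Simulate, write files, run the pipeline; returns list(sim, files, result).
run_sim_pipeline <- function(ref_length, read_length, dup_length, start,
                             allele_fraction = 1.0, coverage = 100,
                             error_rate = 0, seed = 1L, params = itd_params(),
                             targets = NULL, workers = 1L) {
  cfg <- sim_config(ref_length, read_length = read_length,
                    coverage = coverage, error_rate = error_rate,
                    seed = seed,
                    itds = list(truth_itd("chrS", start, dup_length,
                                          allele_fraction)))
  sim <- simulate_reads(cfg)
  files <- write_sim(sim, cfg, tempfile())
  res <- itd_run(files$sam, files$fasta, targets = targets, params = params,
                 workers = workers)
  list(cfg = cfg, sim = sim, files = files, result = res)
}

# A call matching the (left-normalized) truth locus and length exactly.
truth_recovered <- function(result, sim) {
  if (!nrow(result$calls) || !nrow(sim$truth)) return(FALSE)
  tr <- sim$truth[1, ]
  nl <- normalize_dup_locus(sim$reference, tr$start, tr$end)
  any(result$calls$start == nl[1] & result$calls$end == nl[2] &
        result$calls$dup_length == tr$score)
}

## ---- independent oracles -------------------------------------------------

# All-pairs consecutive-occurrence repeat distances, O(|S|^2 k).
oracle_repeat_distances <- function(S, k) {
  n <- nchar(S)
  if (n < k) stop("short")
  starts <- seq_len(n - k + 1L)
  km <- substring(S, starts, starts + k - 1L)
  out <- integer(0)
  for (i in seq_along(km)) {
    for (j in seq_along(km)) {
      if (j <= i) next
      if (km[i] != km[j]) next
      between <- if (j - i < 2) integer(0) else (i + 1L):(j - 1L)
      if (any(km[between] == km[i])) next   # not consecutive occurrences
      out <- c(out, j - i)
    }
  }
  sort(unique(out))
}

# DP over walk length (independent of exponentiation-by-squaring): vertices
# with a closed walk of exactly `i` edges.
oracle_closed_walk <- function(adj, i) {
  n <- nrow(adj)
  if (!n) return(integer(0))
  hits <- logical(n)
  for (v in seq_len(n)) {
    reach <- logical(n)  # reachable from v in exactly s steps
    reach[v] <- TRUE
    for (s in seq_len(i)) {
      nxt <- logical(n)
      for (u in which(reach)) nxt <- nxt | adj[u, ]
      reach <- nxt
      if (!any(reach)) break
    }
    hits[v] <- reach[v]
  }
  which(hits)
}
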