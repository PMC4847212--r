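# Read filters, repeat-distance spectrum analysis, binning.

cand_df <- function(seqs, origin = "unmapped", clip = NA_character_) {
  n <- length(seqs)
  data.frame(read_id = sprintf("r%02d", seq_len(n)),
             qname = sprintf("r%02d", seq_len(n)), sequence = seqs,
             origin = rep_len(origin, n), clip_segment = rep_len(clip, n),
             clip_side = rep_len(NA_character_, n),
             ref_name = rep_len(NA_character_, n),
             pos = rep_len(NA_integer_, n),
             stringsAsFactors = FALSE)
}

test_that("count_base counts occurrences", {
  expect_identical(count_base("", "N"), 0L)
  expect_identical(count_base("ANNA", "N"), 2L)
  expect_identical(count_base("AAAA", "A"), 4L)
})

test_that("N filter boundary sits at the configured maximum", {
  base <- strrep("ACGT", 10)
  r50 <- paste0(base, strrep("N", 50))
  r51 <- paste0(base, strrep("N", 51))
  out <- filter_n(cand_df(c(r50, r51)))
  expect_identical(out$sequence, r50)
  expect_identical(nrow(filter_n(cand_df(character(0)))), 0L)
})

test_that("homopolymer filter boundary sits at runs of 15", {
  pad <- strrep("ACGT", 8)
  r14 <- paste0(pad, strrep("A", 14), "C")
  r15 <- paste0(pad, strrep("A", 15), "C")
  alt <- strrep("AC", 20)
  out <- filter_homopolymer(cand_df(c(r14, r15, alt)))
  expect_setequal(out$sequence, c(r14, alt))
})

test_that("repeat_distances matches hand-derived examples", {
  expect_identical(repeat_distances("ACGTACGTAA", 4), 4L)
  expect_identical(repeat_distances("ACGTTGCA", 4), integer(0))
  expect_identical(repeat_distances("ACGTGACGTGTT", 3), 5L)
  expect_error(repeat_distances("ACG", 4), "shorter")
  expect_error(repeat_distances("ACG", 0), ">= 1")
})

test_that("repeat_distances agrees with the all-pairs oracle", {
  for (s in 1:30) {
    n <- itdscan:::with_seed(s, sample(20:200, 1))
    S <- rand_dna(n, seed = s * 7)
    if (s %% 3 == 0) {  # implant a genuine duplication to exercise repeats
      L <- itdscan:::with_seed(s, sample(4:25, 1))
      st <- itdscan:::with_seed(s + 1, sample(0:(n - L), 1))
      S <- implant_itd(S, st, L)
    }
    k <- itdscan:::with_seed(s + 2, sample(3:8, 1))
    expect_identical(repeat_distances(S, k), oracle_repeat_distances(S, k),
                     label = paste("case", s))
  }
})

test_that("repeat distances are strand-invariant", {
  for (s in 1:15) {
    S <- implant_itd(rand_dna(80, seed = s), 20, 17)
    expect_identical(repeat_distances(S, 5), repeat_distances(revcomp(S), 5))
  }
})

test_that("bin_reads respects the distance range and multi-bin membership", {
  p <- itd_params(p_kmer = 4, d_kmer = 4, r_min = 15, r_max = 61)
  # signature {4} only: excluded by r_min
  r_short <- "ACGTACGTAACCGGTTACGATCGA"
  expect_identical(length(bin_reads(cand_df(r_short), p)), 0L)
  # a 4-mer occurring at positions 0, 20 and 53: distances 20 and 33
  u1 <- "GATC"
  r_multi <- paste0(u1, rand_dna(16, seed = 98), u1,
                    rand_dna(29, seed = 99), u1)
  d <- repeat_distances(r_multi, 4)
  expect_true(all(c(20L, 33L) %in% d))
  bins <- bin_reads(cand_df(r_multi), p)
  expect_true(all(c("20", "33") %in% names(bins)))
  expect_identical(bins[["20"]]$read_id, bins[["33"]]$read_id)
})

test_that("soft-clipped reads are scanned for the clip segment only", {
  clip <- "GATTACAGGC"
  filler1 <- "TTTGGGCCCAAATTG"                       # 15 bp
  seqs <- paste0(clip, filler1, clip, rand_dna(30, seed = 4))  # clip at 0, 25
  p <- itd_params(p_kmer = 10, d_kmer = 10, r_min = 15, r_max = 61)
  df <- cand_df(seqs, origin = "softclip", clip = clip)
  bins <- bin_reads(df, p)
  expect_identical(names(bins), "25")
  # the same sequence treated as unmapped may hit other distances too
  df2 <- cand_df(seqs, origin = "unmapped")
  expect_true("25" %in% names(bin_reads(df2, p)))
})

test_that("filters only remove and N/homopolymer commute", {
  cfg <- sim_config(400, read_length = 60, coverage = 40, error_rate = 0.01,
                    seed = 3, itds = list(truth_itd("chrS", 150, 25, 0.8)))
  sim <- simulate_reads(cfg)
  df <- cand_df(sim$reads$seq[sim$reads$status == "unmapped"])
  a <- filter_n(df); b <- filter_homopolymer(a)
  expect_true(all(b$read_id %in% a$read_id) && all(a$read_id %in% df$read_id))
  b2 <- filter_n(filter_homopolymer(df))
  expect_identical(b, b2)
})

test_that("itd_params validates its invariants", {
  expect_error(itd_params(p_kmer = 10, d_kmer = 8))    # d_kmer < p_kmer
  expect_error(itd_params(p_kmer = 10, r_min = 5))     # r_min < p_kmer
  expect_error(itd_params(r_min = 30, r_max = 20))
  expect_error(itd_params(cov_cutoff_min = 10, cov_cutoff_max = 5))
  fl <- itd_params(preset = "flt3")
  expect_identical(fl$p_kmer, 15L)
  expect_identical(fl$cov_cutoff_min, 30L)
  expect_identical(fl$r_max, 85L)
})
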