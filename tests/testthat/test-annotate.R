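# Duplicated-kmer detection, collapse, alignment, classification,
# allele fraction, RNA validation, BED round trip.

test_that("find_duplicated_kmer returns the leftmost in-range pair", {
  hit <- find_duplicated_kmer("ACGTGACGTGTT", 3, 4, 10)
  expect_identical(hit[c("p1", "p2")], list(p1 = 0L, p2 = 5L))
  expect_identical(hit$kmer, "ACG")
  expect_null(find_duplicated_kmer("ACGTTGCA", 3, 4, 10))
  expect_null(find_duplicated_kmer("ACGACG", 3, 4, 10))  # distance 3 < r_min
})

test_that("collapse_duplication deletes the inter-kmer region", {
  expect_identical(collapse_duplication("ACGTGACGTGTT", 0, 5), "ACGTGTT")
  expect_error(collapse_duplication("ACGT", 2, 2), "range")
  expect_error(collapse_duplication("ACGT", -1, 2), "range")
  # on simulated contigs, collapsing the full duplication recovers reference
  ref <- make_reference(300, seed = 15)
  allele <- implant_itd(ref, 120, 25)
  contig <- substr(allele, 96, 200)
  hit <- find_duplicated_kmer(contig, 10, 15, 61)
  expect_identical(hit$p2 - hit$p1, 25L)
  col <- collapse_duplication(contig, hit$p1, hit$p2)
  expect_true(grepl(col, ref, fixed = TRUE))
})

test_that("align_collapsed accepts unique loci and rejects ambiguity", {
  ref <- make_reference(2000, seed = 8)
  q <- substr(ref, 501, 560)
  aln <- align_collapsed(q, c(chr1 = ref))
  expect_s3_class(aln, "itd_alignment")
  expect_identical(aln$ref_start, 500L)
  expect_identical(aln$ref_end, 560L)
  expect_identical(aln$identity, 1)
  expect_identical(aln$strand, "+")
  # reverse-complement queries align on the minus strand
  aln_rc <- align_collapsed(revcomp(q), c(chr1 = ref))
  expect_identical(aln_rc$ref_start, 500L)
  expect_identical(aln_rc$strand, "-")
  # segment present twice -> fails the specificity margin
  seg <- substr(ref, 101, 160)
  dupref <- paste0(ref, seg, substr(make_reference(100, seed = 9), 1, 100))
  expect_null(align_collapsed(seg, c(chr1 = dupref)))
  # random query absent from the reference
  expect_null(align_collapsed(rand_dna(60, seed = 77), c(chr1 = ref)))
})

test_that("classify_call separates insertion classes and capture overlap", {
  ref <- make_reference(1500, seed = 22)
  q <- substr(ref, 701, 800)
  aln <- align_collapsed(q, c(chrS = ref))
  targets <- data.frame(chrom = "chrS", start = 650L, end = 850L,
                        name = "FLT3_e14", stringsAsFactors = FALSE)
  cl <- classify_call(aln, 20L, 30L, targets)
  expect_identical(cl$classification, "coding_ITD")
  expect_identical(cl$gene, "FLT3_e14")
  expect_identical(cl$start, 720L)
  expect_identical(cl$end, 750L)
  # same call, targets elsewhere -> off_target
  far <- data.frame(chrom = "chrS", start = 10L, end = 50L, name = "OTHER")
  expect_identical(classify_call(aln, 20L, 30L, far)$classification,
                   "off_target")
  # no targets -> intronic (unannotated insertion)
  expect_identical(classify_call(aln, 20L, 30L, NULL)$classification,
                   "intronic")
  # a large internal reference gap -> non_insertion
  gappy <- structure(c(aln[setdiff(names(aln), "max_ref_gap")],
                       list(max_ref_gap = 50L)), class = "itd_alignment")
  expect_identical(classify_call(gappy, 20L, 30L, targets)$classification,
                   "non_insertion")
})

test_that("allele_fraction is support over depth", {
  expect_identical(allele_fraction(0, 100), 0)
  expect_identical(allele_fraction(30, 150), 0.2)
  expect_warning(af <- allele_fraction(0, 0), "zero depth")
  expect_true(is.na(af))
  expect_error(allele_fraction(10, 5))
})

test_that("normalize_dup_locus left-aligns ambiguous breakpoints", {
  #       0123456789
  ref <- "TTACGACGTT"   # ACG duplicated at [2,5) and [5,8)
  expect_identical(normalize_dup_locus(ref, 5L, 8L), c(2L, 5L))
  expect_identical(normalize_dup_locus(ref, 2L, 5L), c(2L, 5L))
  ref2 <- "GATTACAGGC"
  expect_identical(normalize_dup_locus(ref2, 4L, 7L), c(4L, 7L))
})

test_that("rna_validate needs identity, junction span and expression", {
  ref <- make_reference(400, seed = 44)
  contig <- implant_itd(ref, 180, 30)   # junction at 210
  contig <- substr(contig, 151, 280)
  junction <- 60L                       # 180+30 in contig coords (0-based)
  mk_reads <- function(n, mut = 0L) {
    starts <- round(seq(20, 55, length.out = n))  # all span junction +/- 5
    vapply(starts, function(st) {
      s <- substr(contig, st, st + 49)
      if (mut > 0) {
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        pos <- round(seq(2, 48, length.out = mut))
        ch[pos] <- vapply(ch[pos], function(b)
          setdiff(c("A", "C", "G", "T"), b)[1], character(1))
        s <- paste(ch, collapse = "")
      }
      s
    }, character(1))
  }
  good <- rna_validate(contig, junction, mk_reads(12))
  expect_identical(good$junction_reads, 12L)
  expect_true(good$validated)
  # low-identity reads never count as aligned
  bad <- rna_validate(contig, junction, mk_reads(12, mut = 5))
  expect_false(bad$validated)
  expect_identical(bad$n_aligned, 0L)
  # expression below 10 aligned reads: not evaluable
  few <- rna_validate(contig, junction, mk_reads(9))
  expect_false(few$evaluable)
  expect_false(few$validated)
})

test_that("merge_calls dedupes by locus+length keeping max support", {
  calls <- data.frame(
    ref_name = "chrS", start = c(100L, 100L, 100L), end = c(130L, 130L, 145L),
    dup_length = c(30L, 30L, 45L), classification = "coding_ITD",
    gene = "FLT3", support_reads = c(12L, 20L, 9L), depth = c(50L, 60L, 40L),
    allele_fraction = c(0.24, 1 / 3, 0.225), contig_id = c("c1", "c2", "c3"),
    junction_offset = c(40L, 41L, 40L), stringsAsFactors = FALSE)
  out <- merge_calls(calls)
  expect_identical(nrow(out), 2L)          # bi-allelic lengths both retained
  expect_identical(out$support_reads[out$dup_length == 30], 20L)
  expect_identical(merge_calls(calls[0, ]), calls[0, ])
})

test_that("BED writer/reader round trip is lossless", {
  calls <- data.frame(
    ref_name = c("chrS", "chrS"), start = c(100L, 300L), end = c(130L, 340L),
    dup_length = c(30L, 40L), classification = c("coding_ITD", "intronic"),
    gene = c("FLT3", NA), support_reads = c(20L, 7L), depth = c(60L, 20L),
    allele_fraction = c(1 / 3, 0.35), contig_id = c("ctg0001", "ctg0002"),
    junction_offset = c(40L, 55L), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".bed")
  write_itd_bed(calls, path, params = itd_params())
  back <- read_itd_bed(path)
  for (col in c("ref_name", "start", "end", "dup_length", "support_reads",
                "allele_fraction", "classification", "contig_id",
                "junction_offset", "gene")) {
    expect_equal(back[[col]], calls[[col]], label = col)
  }
  # empty call set still round-trips
  write_itd_bed(calls[0, ], path)
  expect_identical(nrow(read_itd_bed(path)), 0L)
})
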