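# End-to-end pipeline: extract -> filter/bin -> (optional) cycle filter ->
# assemble -> annotate, with a per-stage run report.

# Annotate one contig: find duplicated kmer pair(s), collapse (iterating to
# expose complex events), align once, emit one call row per event.
.annotate_contig <- function(contig, params, reference, targets,
                             depth_fun = NULL) {
  events <- list()
  seqc <- contig$sequence
  max_iter <- 3L
  for (it in seq_len(max_iter)) {
    if (nchar(seqc) < params$d_kmer) break
    hit <- find_duplicated_kmer(seqc, params$d_kmer, params$r_min,
                                params$r_max)
    if (is.null(hit)) break
    dl <- hit$p2 - hit$p1
    # shift previously recorded events right of the removed block
    for (e in seq_along(events)) {
      if (events[[e]]$p1 >= hit$p2) events[[e]]$p1 <- events[[e]]$p1 - dl
    }
    events[[length(events) + 1L]] <-
      list(p1 = hit$p1, p2_orig = hit$p2, dup_length = dl)
    seqc <- collapse_duplication(seqc, hit$p1, hit$p2)
  }
  if (!length(events)) return(NULL)
  aln <- align_collapsed(seqc, reference)
  if (is.null(aln)) return(NULL)
  rows <- list()
  for (e in events) {
    cl <- classify_call(aln, e$p1, e$dup_length, targets, k = params$d_kmer)
    if (is.null(cl)) next
    if (!is.na(cl$start) && cl$ref_name %in% names(reference)) {
      nl <- normalize_dup_locus(reference[[cl$ref_name]], cl$start, cl$end)
      cl$start <- nl[1L]; cl$end <- nl[2L]
    }
    junction <- e$p2_orig                       # contig coord, second copy
    lay <- contig$layout
    support <- sum(lay$offset <= junction - 5L &
                     lay$offset + lay$length >= junction + 6L)
    depth_other <- if (is.null(depth_fun)) 0L else
      depth_fun(cl$ref_name, cl$end)
    depth <- depth_other + support
    cl$support_reads <- support
    cl$depth <- depth
    cl$allele_fraction <- if (depth > 0) support / depth else NA_real_
    cl$contig_id <- contig$contig_id
    cl$junction_offset <- junction
    rows[[length(rows) + 1L]] <- cl
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

.empty_calls <- function() data.frame(
  ref_name = character(0), start = integer(0), end = integer(0),
  dup_length = integer(0), classification = character(0),
  gene = character(0), support_reads = integer(0), depth = integer(0),
  allele_fraction = numeric(0), contig_id = character(0),
  junction_offset = integer(0), stringsAsFactors = FALSE)

# Process one bin into call rows (possibly none).
.process_bin <- function(i, bindf, params, reference, targets, depth_fun,
                         dump_contigs = NULL) {
  if (!params$light) {
    g <- build_debruijn(bindf$sequence, params$d_kmer,
                        params$cov_cutoff_min, params$cov_cutoff_max)
    ck <- closed_walk_vertices(g, i)
    bindf <- filter_reads_by_cycle(bindf, ck, params$d_kmer)
  }
  n_after_cycle <- nrow(bindf)
  calls <- .empty_calls()
  n_contigs <- 0L
  if (nrow(bindf)) {
    contigs <- greedy_assemble(bindf, params$min_overlap,
                               params$min_identity)
    n_contigs <- length(contigs)
    rows <- lapply(contigs, .annotate_contig, params = params,
                   reference = reference, targets = targets,
                   depth_fun = depth_fun)
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) calls <- do.call(rbind, rows)
    if (!is.null(dump_contigs)) {
      jn <- stats::setNames(calls$junction_offset, calls$contig_id)
      seqs <- Biostrings::DNAStringSet(
        vapply(contigs, `[[`, character(1), "sequence"))
      names(seqs) <- vapply(contigs, function(cg) {
        j <- if (cg$contig_id %in% names(jn)) jn[[cg$contig_id]] else NA
        paste0("bin", i, ".", cg$contig_id,
               if (!is.na(j)) paste0(" junction=", j) else "")
      }, character(1))
      Biostrings::writeXStringSet(
        seqs, file.path(dump_contigs, sprintf("bin%d.contigs.fa", i)))
    }
  }
  list(bin = i, after_cycle = n_after_cycle, contigs = n_contigs,
       calls = calls)
}

#' Run the full ITD detection pipeline
#'
#' Extracts unmapped and soft-clipped candidate reads, applies the N and
#' homopolymer filters, bins reads by duplicated-kmer repeat distance,
#' optionally confirms each bin through De Bruijn closed-walk detection,
#' assembles each bin with the greedy OLC assembler, and annotates contigs
#' against the reference (and capture targets, when given). Insertion-type
#' calls are reported; `non_insertion` and `off_target` events are counted
#' in the report but dropped from the call set.
#'
#' @param alignment_file SAM or BAM file with unmapped reads retained.
#' @param reference reference FASTA path, or a named character vector of
#'   sequences.
#' @param targets optional capture targets: BED path (columns chrom, start,
#'   end, name) or an equivalent data.frame. Calls outside targets are
#'   dropped as `off_target`.
#' @param params an [itd_params()] object.
#' @param workers number of worker processes for per-bin stages (the call
#'   set is identical to a serial run).
#' @param dump_contigs optional directory; per-bin contig FASTA files
#'   (`bin<i>.contigs.fa`, records named `<contig_id> junction=<offset>`)
#'   are written there for downstream use such as RNA validation.
#' @return list of class `itd_result`: `calls` (data.frame) and `report`
#'   (per-stage counters, parameter echo, timings).
#' @export
itd_run <- function(alignment_file, reference, targets = NULL,
                    params = itd_params(), workers = 1L,
                    dump_contigs = NULL) {
  stopifnot(inherits(params, "itd_params"))
  t_start <- proc.time()[["elapsed"]]
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference) && is.null(names(reference))) {
    rset <- Biostrings::readDNAStringSet(reference)
    reference <- stats::setNames(as.character(rset),
                                 sub("\\s.*$", "", names(rset)))
  }
  if (is.character(targets) && length(targets) == 1L) {
    targets <- utils::read.table(targets, sep = "\t",
                                 stringsAsFactors = FALSE)[, 1:4]
    names(targets) <- c("chrom", "start", "end", "name")
  }
  bam <- ensure_bam(alignment_file)
  cands <- extract_candidates(bam, params$min_clip)
  t_extract <- proc.time()[["elapsed"]]
  f1 <- filter_n(cands, params$max_n)
  f2 <- filter_homopolymer(f1, params$max_homopolymer)
  # bins above read_length - p_kmer cannot carry a within-read signature
  eff <- params
  if (nrow(f2)) {
    cap <- max(nchar(f2$sequence)) - params$p_kmer
    if (eff$r_max > cap) eff$r_max <- max(cap, eff$r_min)
  }
  bins <- bin_reads(f2, eff)
  t_bin <- proc.time()[["elapsed"]]
  ref_lens <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  depth_fun <- function(ref_name, pos) {
    if (!ref_name %in% names(ref_lens)) return(0L)
    pos <- max(0L, min(as.integer(pos), ref_lens[[ref_name]] - 1L))
    tryCatch(hard_filtered_depth(bam, ref_name, pos),
             error = function(e) 0L)
  }
  bin_lengths <- as.integer(names(bins))
  if (!is.null(dump_contigs))
    dir.create(dump_contigs, recursive = TRUE, showWarnings = FALSE)
  worker <- function(j) .process_bin(bin_lengths[j], bins[[j]], eff,
                                     reference, targets, depth_fun,
                                     dump_contigs)
  res <- if (workers > 1L && length(bins)) {
    parallel::mclapply(seq_along(bins), worker, mc.cores = workers)
  } else {
    lapply(seq_along(bins), worker)
  }
  t_asm <- proc.time()[["elapsed"]]
  all_calls <- if (length(res)) {
    do.call(rbind, lapply(res, `[[`, "calls"))
  } else .empty_calls()
  n_raw <- nrow(all_calls)
  dropped <- all_calls$classification %in% c("non_insertion", "off_target")
  calls <- merge_calls(all_calls[!dropped, , drop = FALSE])
  binned_ids <- unique(unlist(lapply(bins, `[[`, "read_id")))
  report <- list(
    extracted = nrow(cands),
    after_n_filter = nrow(f1),
    after_homopolymer_filter = nrow(f2),
    after_spectrum = length(binned_ids),
    n_bins = length(bins),
    per_bin = data.frame(
      bin = bin_lengths,
      reads = vapply(bins, nrow, integer(1), USE.NAMES = FALSE),
      after_cycle = vapply(res, `[[`, integer(1), "after_cycle"),
      contigs = vapply(res, `[[`, integer(1), "contigs")),
    raw_calls = n_raw,
    dropped_non_insertion = sum(all_calls$classification == "non_insertion"),
    dropped_off_target = sum(all_calls$classification == "off_target"),
    calls = nrow(calls),
    params = eff,
    timings = c(extract = t_extract - t_start, bin = t_bin - t_extract,
                assemble_annotate = t_asm - t_bin))
  structure(list(calls = calls, report = report), class = "itd_result")
}

#' @export
print.itd_result <- function(x, ...) {
  r <- x$report
  cat("ITD detection run\n")
  cat(sprintf("  candidates extracted : %d\n", r$extracted))
  cat(sprintf("  after N filter       : %d\n", r$after_n_filter))
  cat(sprintf("  after homopolymer    : %d\n", r$after_homopolymer_filter))
  cat(sprintf("  with repeat signature: %d (in %d bins)\n",
              r$after_spectrum, r$n_bins))
  cat(sprintf("  calls                : %d\n", r$calls))
  if (nrow(x$calls)) {
    print(x$calls[, c("ref_name", "start", "end", "dup_length",
                      "classification", "gene", "support_reads", "depth",
                      "allele_fraction")])
  }
  invisible(x)
}
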