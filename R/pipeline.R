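#' Merge a batch of read pairs
#'
#' Runs the full inference on each pair: posterior over molecule
#' lengths, ambiguity guard, and — when a length hypothesis wins —
#' consensus assembly of the reconstructed molecule. This is the
#' in-memory work-horse behind [run_merge()]; use it directly when the
#' reads are already in R.
#'
#' @param r1,r2 Lists of [read_record()]s of equal length (mates in the
#'   same order; `r2` as sequenced).
#' @param adaptors An [adaptor_pair()].
#' @param prior A [length_prior()].
#' @param ratio_threshold Ambiguity guard passed to [decide()].
#' @param qual_cap Consensus quality cap passed to [merge_pair()].
#' @param profile_out Optional path; when given, every pair's candidate
#'   lengths and log posteriors are appended there as TSV
#'   (columns `id`, `hypothesis`, `log_posterior`) for landscape plots.
#' @return A list of class `merge_batch`: `results` (one `merge_result`
#'   per pair, with `sequence` filled in for merged pairs) and `summary`
#'   (named counts: `merged`, `ambiguous`, `kept_as_pair`,
#'   `trimmed_single`).
#' @export
merge_reads <- function(r1, r2, adaptors = adaptor_pair(),
                        prior = length_prior("uniform"),
                        ratio_threshold = 0.05, qual_cap = 60L,
                        profile_out = NULL) {
  stopifnot(is.list(r1), is.list(r2), length(r1) == length(r2))
  n <- length(r1)
  results <- vector("list", n)
  con <- NULL
  if (!is.null(profile_out)) {
    con <- file(profile_out, "w")
    on.exit(close(con))
    writeLines("id\thypothesis\tlog_posterior", con)
  }
  for (k in seq_len(n)) {
    prof <- posterior_profile(r1[[k]], r2[[k]], adaptors, prior)
    res <- decide(prof, ratio_threshold)
    if (res$decision == "merged") {
      res$sequence <- merge_pair(r1[[k]], r2[[k]], res$inferred_length,
                                 qual_cap = qual_cap)
    }
    attr(res, "combined_read_len") <- prof$l1 + prof$l2
    results[[k]] <- res
    if (!is.null(con)) {
      df <- as.data.frame(prof)
      writeLines(sprintf("%s\t%s\t%.6f", r1[[k]]$id, df$hypothesis,
                         df$log_posterior), con)
    }
  }
  .batch(results)
}

#' Trim a batch of single-end reads
#'
#' Single-end analogue of [merge_reads()]: infers the adaptor start
#' position per read and cuts the read there when a trim point wins.
#'
#' @param reads List of [read_record()]s.
#' @param adaptor Adaptor string expected at the 3' end.
#' @inheritParams merge_reads
#' @return A `merge_batch` as in [merge_reads()]; trimmed reads carry
#'   decision `"trimmed_single"`, reads best explained as
#'   molecule-longer-than-read are `"kept_as_pair"` (passed through).
#' @export
trim_reads <- function(reads, adaptor = DEFAULT_ADAPTOR1,
                       prior = length_prior("uniform"),
                       ratio_threshold = 0.05, profile_out = NULL) {
  stopifnot(is.list(reads))
  results <- vector("list", length(reads))
  con <- NULL
  if (!is.null(profile_out)) {
    con <- file(profile_out, "w")
    on.exit(close(con))
    writeLines("id\thypothesis\tlog_posterior", con)
  }
  for (k in seq_along(reads)) {
    prof <- single_end_profile(reads[[k]], adaptor, prior)
    res <- decide(prof, ratio_threshold)
    if (res$decision == "trimmed_single") {
      i <- res$inferred_length
      res$sequence <- read_record(reads[[k]]$id,
                                  substr(reads[[k]]$bases, 1L, i),
                                  reads[[k]]$quals[seq_len(i)])
    }
    attr(res, "combined_read_len") <- prof$l1
    results[[k]] <- res
    if (!is.null(con)) {
      df <- as.data.frame(prof)
      writeLines(sprintf("%s\t%s\t%.6f", reads[[k]]$id, df$hypothesis,
                         df$log_posterior), con)
    }
  }
  .batch(results)
}

.batch <- function(results) {
  dec <- vapply(results, `[[`, character(1), "decision")
  out <- list(results = results,
              summary = c(merged = sum(dec == "merged"),
                          ambiguous = sum(dec == "ambiguous"),
                          kept_as_pair = sum(dec == "kept_as_pair"),
                          trimmed_single = sum(dec == "trimmed_single")))
  class(out) <- "merge_batch"
  out
}

#' @export
print.merge_batch <- function(x, ...) {
  cat("<merge_batch> ", length(x$results), " records\n", sep = "")
  s <- x$summary
  for (nm in names(s)) cat(sprintf("  %-15s %d\n", nm, s[[nm]]))
  invisible(x)
}

#' Run the merge pipeline on files
#'
#' File-level front end: reads pairs (or single reads) from FASTQ or
#' unaligned BAM, runs [merge_reads()] (or [trim_reads()]), and routes
#' the outcomes to output files: merged/trimmed sequences as single
#' records, ambiguous and kept pairs passed through as pairs. Per-
#' outcome counts are printed to standard error and returned.
#'
#' @param fq1,fq2 Paired FASTQ paths (plain or gzip).
#' @param fqi Interleaved FASTQ path (alternative to `fq1`/`fq2`).
#' @param bam_in Unaligned BAM path (alternative input).
#' @param out Output FASTQ path for merged/trimmed sequences.
#' @param unmerged_prefix Prefix for pass-through pair FASTQs
#'   (`<prefix>_r1.fq`, `<prefix>_r2.fq`); defaults next to `out`.
#' @param bam_out Output BAM path; when given, all outcomes go into one
#'   BAM, each record tagged `dc:A:` `M`erged, `A`mbiguous, `K`ept or
#'   `T`rimmed.
#' @param single Logical; treat input as single-end and trim only.
#' @param adaptors,prior,ratio_threshold,qual_cap,profile_out Passed to
#'   [merge_reads()] / [trim_reads()].
#' @param offset PHRED offset of FASTQ input and output.
#' @param verbose Print per-pair log-odds to standard error.
#' @return Invisibly, the `merge_batch` with an added `files` element.
#' @export
run_merge <- function(fq1 = NULL, fq2 = NULL, fqi = NULL, bam_in = NULL,
                      out = NULL, unmerged_prefix = NULL, bam_out = NULL,
                      single = FALSE, adaptors = adaptor_pair(),
                      prior = length_prior("uniform"),
                      ratio_threshold = 0.05, qual_cap = 60L,
                      offset = 33L, profile_out = NULL, verbose = FALSE) {
  modes <- c(!is.null(fq1), !is.null(fqi), !is.null(bam_in))
  if (sum(modes) != 1L) {
    stop("select exactly one input mode: fq1/fq2, fqi, or bam_in")
  }
  if (single) {
    reads <- if (!is.null(fq1)) read_fastq(fq1, offset = offset)
             else if (!is.null(fqi)) read_fastq(fqi, offset = offset)
             else read_bam_single(bam_in)
    batch <- trim_reads(reads, adaptor = adaptors$a1, prior = prior,
                        ratio_threshold = ratio_threshold,
                        profile_out = profile_out)
    inputs <- list(r1 = reads, r2 = NULL)
  } else {
    inputs <- if (!is.null(fq1)) {
      if (is.null(fq2)) stop("paired FASTQ input needs both fq1 and fq2")
      read_pairs_fastq(fq1, fq2, offset = offset)
    } else if (!is.null(fqi)) {
      read_pairs_interleaved(fqi, offset = offset)
    } else {
      read_pairs_bam(bam_in)
    }
    batch <- merge_reads(inputs$r1, inputs$r2, adaptors = adaptors,
                         prior = prior,
                         ratio_threshold = ratio_threshold,
                         qual_cap = qual_cap, profile_out = profile_out)
  }
  if (verbose) {
    for (r in batch$results) {
      message(sprintf("%s\t%s\tlog_odds=%.3f",
                      if (!is.null(r$sequence)) r$sequence$id else "-",
                      r$decision, r$log_odds))
    }
  }
  files <- write_results(batch, inputs$r1, inputs$r2, out = out,
                         unmerged_prefix = unmerged_prefix,
                         bam_out = bam_out, offset = offset)
  s <- batch$summary
  message(sprintf(
    "processed %d records: %d merged, %d ambiguous, %d kept as pair, %d trimmed",
    length(batch$results), s[["merged"]], s[["ambiguous"]],
    s[["kept_as_pair"]], s[["trimmed_single"]]))
  batch$files <- files
  invisible(batch)
}
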