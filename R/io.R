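## FASTQ and unaligned BAM input/output.
##
## FASTQ parsing/decoding is delegated to Biostrings (gzip transparent),
## BAM to Rsamtools; records are converted to plain read_record lists at
## the package boundary. PHRED+33 is the default FASTQ encoding, +64
## supported via `offset`.

.scoring_for_offset <- function(offset) {
  if (offset == 33L) "phred"
  else if (offset == 64L) "illumina"
  else stop("unsupported PHRED offset: ", offset, " (use 33 or 64)")
}

## canonical mate id: drop comment and trailing /1 /2
.strip_mate <- function(id) sub("/[12]$", "", sub("\\s.*$", "", id))

#' Read a FASTQ file into read records
#'
#' @param path FASTQ path, plain or gzip.
#' @param offset PHRED offset of the encoding (33 or 64).
#' @return A list of [read_record()]s in file order.
#' @export
read_fastq <- function(path, offset = 33L) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- tryCatch(
    ## Biostrings warns about dropping its own metadata columns while
    ## assembling the quality-scaled set; nothing of ours is lost
    withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(
        path, quality.scoring = .scoring_for_offset(offset)),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }),
    error = function(e) stop("failed to parse FASTQ '", path, "': ",
                             conditionMessage(e)))
  ids <- names(x)
  ## as.character on a quality-scaled set warns about dropping the
  ## quality metadata; the qualities are extracted separately below
  seqs <- unname(suppressWarnings(as.character(x)))
  quals <- as(Biostrings::quality(x), "IntegerList")
  lapply(seq_along(x), function(k) {
    read_record(ids[k], seqs[k], quals[[k]])
  })
}

#' Write read records to a FASTQ file
#'
#' @param reads List of [read_record()]s.
#' @param path Output path; gzip-compressed when it ends in `.gz`.
#' @param offset PHRED offset; qualities are clamped to the encodable
#'   range of the offset.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path, offset = 33L) {
  .scoring_for_offset(offset)
  qmax <- if (offset == 33L) 93L else 62L
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(reads) > 0L) {
    lines <- vapply(reads, function(r) {
      q <- pmin(pmax(r$quals, 0L), qmax)
      paste0("@", r$id, "\n", r$bases, "\n+\n",
             intToUtf8(q + offset, multiple = FALSE))
    }, character(1))
    writeLines(lines, con)
  }
  invisible(path)
}

.check_mates <- function(id1, id2) {
  m1 <- .strip_mate(id1)
  m2 <- .strip_mate(id2)
  bad <- which(m1 != m2)
  if (length(bad) > 0L) {
    stop("mate identifier mismatch at record ", bad[1L], ": '",
         id1[bad[1L]], "' vs '", id2[bad[1L]], "'")
  }
  invisible(TRUE)
}

#' Read a pair of FASTQ files as mate pairs
#'
#' @param fq1,fq2 FASTQ paths for read 1 and read 2.
#' @param offset PHRED offset.
#' @return A list with elements `r1` and `r2`, lists of
#'   [read_record()]s; an error names the first record whose mate
#'   identifiers disagree (after stripping `/1`, `/2` and comments).
#' @export
read_pairs_fastq <- function(fq1, fq2, offset = 33L) {
  r1 <- read_fastq(fq1, offset = offset)
  r2 <- read_fastq(fq2, offset = offset)
  if (length(r1) != length(r2)) {
    stop("mate files differ in record count: ", length(r1), " vs ",
         length(r2))
  }
  .check_mates(vapply(r1, `[[`, character(1), "id"),
               vapply(r2, `[[`, character(1), "id"))
  list(r1 = r1, r2 = r2)
}

#' Read an interleaved FASTQ file as mate pairs
#'
#' Records alternate read 1 / read 2; an odd record count is an error.
#'
#' @param fqi Interleaved FASTQ path.
#' @param offset PHRED offset.
#' @return As [read_pairs_fastq()].
#' @export
read_pairs_interleaved <- function(fqi, offset = 33L) {
  reads <- read_fastq(fqi, offset = offset)
  if (length(reads) %% 2L != 0L) {
    stop("interleaved FASTQ '", fqi, "' has an odd number of records (",
         length(reads), ")")
  }
  odd <- seq(1L, length(reads), by = 2L)
  r1 <- reads[odd]
  r2 <- reads[odd + 1L]
  .check_mates(vapply(r1, `[[`, character(1), "id"),
               vapply(r2, `[[`, character(1), "id"))
  list(r1 = r1, r2 = r2)
}

.scan_unaligned_bam <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "seq", "qual"))
  Rsamtools::scanBam(path, param = p)[[1L]]
}

.bam_records <- function(b, idx) {
  seqs <- unname(as.character(b$seq[idx]))
  quals <- as(b$qual[idx], "IntegerList")
  ids <- b$qname[idx]
  lapply(seq_along(idx), function(k) read_record(ids[k], seqs[k],
                                                 quals[[k]]))
}

#' Read mate pairs from an unaligned BAM file
#'
#' Pairs are matched by the first/last-mate flag bits; records must come
#' in complete pairs (the usual layout of unaligned BAM, mates
#' adjacent).
#'
#' @param path BAM path.
#' @return As [read_pairs_fastq()].
#' @export
read_pairs_bam <- function(path) {
  b <- .scan_unaligned_bam(path)
  first <- bitwAnd(b$flag, 64L) > 0L
  last <- bitwAnd(b$flag, 128L) > 0L
  if (sum(first) != sum(last)) {
    stop("BAM '", path, "': unequal numbers of first (", sum(first),
         ") and last (", sum(last), ") mates")
  }
  r1 <- .bam_records(b, which(first))
  r2 <- .bam_records(b, which(last))
  .check_mates(vapply(r1, `[[`, character(1), "id"),
               vapply(r2, `[[`, character(1), "id"))
  list(r1 = r1, r2 = r2)
}

#' Read single-end records from an unaligned BAM file
#'
#' @param path BAM path.
#' @return A list of [read_record()]s.
#' @export
read_bam_single <- function(path) {
  b <- .scan_unaligned_bam(path)
  .bam_records(b, seq_along(b$qname))
}

.sam_line <- function(id, bases, quals, flag, tag, offset = 33L) {
  q <- pmin(pmax(quals, 0L), 93L)
  qs <- if (length(q) == 0L) "*" else intToUtf8(q + 33L, multiple = FALSE)
  paste(id, flag, "*", 0L, 0L, "*", "*", 0L, 0L,
        if (nchar(bases) == 0L) "*" else bases, qs,
        paste0("dc:A:", tag), sep = "\t")
}

#' Write merge outcomes to an unaligned BAM file
#'
#' Every input record is written exactly once: merged and trimmed
#' sequences as single unmapped records, ambiguous and kept pairs as
#' unmapped mate pairs. The decision is recorded in the `dc` aux tag
#' (`A` type): `M` merged, `A` ambiguous, `K` kept as pair, `T` trimmed.
#'
#' @param batch A `merge_batch` from [merge_reads()] / [trim_reads()].
#' @param r1,r2 The input records the batch was computed from (`r2`
#'   `NULL` for single-end).
#' @param path Output BAM path.
#' @return Invisibly, `path`.
#' @export
write_bam_results <- function(batch, r1, r2, path) {
  lines <- c("@HD\tVN:1.6\tSO:unknown")
  for (k in seq_along(batch$results)) {
    res <- batch$results[[k]]
    tag <- c(merged = "M", ambiguous = "A", kept_as_pair = "K",
             trimmed_single = "T")[[res$decision]]
    if (res$decision %in% c("merged", "trimmed_single")) {
      s <- res$sequence
      lines <- c(lines, .sam_line(s$id, s$bases, s$quals, 4L, tag))
    } else if (is.null(r2)) {
      r <- r1[[k]]
      lines <- c(lines, .sam_line(r$id, r$bases, r$quals, 4L, tag))
    } else {
      a <- r1[[k]]
      b <- r2[[k]]
      lines <- c(lines,
                 .sam_line(a$id, a$bases, a$quals, 77L, tag),
                 .sam_line(b$id, b$bases, b$quals, 141L, tag))
    }
  }
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam))
  writeLines(lines, sam)
  dest <- sub("\\.bam$", "", path)
  Rsamtools::asBam(sam, dest, overwrite = TRUE, indexDestination = FALSE)
  invisible(path)
}

#' Route merge outcomes to output files
#'
#' FASTQ mode (default): merged/trimmed sequences go to `out`,
#' ambiguous and kept records are passed through unmodified to
#' `<unmerged_prefix>_r1.fq` / `_r2.fq`. BAM mode (`bam_out` given):
#' everything goes into one decision-tagged BAM
#' ([write_bam_results()]). Every input record appears exactly once
#' across the outputs.
#'
#' @inheritParams write_bam_results
#' @param out Merged-output FASTQ path (default `merged.fq` next to the
#'   prefix).
#' @param unmerged_prefix Path prefix for pass-through records.
#' @param bam_out Output BAM path (switches to BAM mode).
#' @param offset PHRED offset for FASTQ output.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_results <- function(batch, r1, r2 = NULL, out = NULL,
                          unmerged_prefix = NULL, bam_out = NULL,
                          offset = 33L) {
  if (!is.null(bam_out)) {
    write_bam_results(batch, r1, r2, bam_out)
    return(invisible(c(bam = bam_out)))
  }
  if (is.null(out)) out <- "merged.fq"
  if (is.null(unmerged_prefix)) {
    unmerged_prefix <- sub("\\.(fq|fastq)(\\.gz)?$", "", out)
  }
  dec <- vapply(batch$results, `[[`, character(1), "decision")
  done <- dec %in% c("merged", "trimmed_single")
  write_fastq(lapply(batch$results[done], `[[`, "sequence"), out,
              offset = offset)
  files <- c(merged = out)
  pass <- which(!done)
  ext <- if (grepl("\\.gz$", out)) ".fq.gz" else ".fq"
  if (is.null(r2)) {
    f1 <- paste0(unmerged_prefix, "_untrimmed", ext)
    write_fastq(r1[pass], f1, offset = offset)
    files <- c(files, untrimmed = f1)
  } else {
    f1 <- paste0(unmerged_prefix, "_r1", ext)
    f2 <- paste0(unmerged_prefix, "_r2", ext)
    write_fastq(r1[pass], f1, offset = offset)
    write_fastq(r2[pass], f2, offset = offset)
    files <- c(files, unmerged_r1 = f1, unmerged_r2 = f2)
  }
  invisible(files)
}
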