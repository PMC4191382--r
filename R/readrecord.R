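#' Construct a sequencing read record
#'
#' A read record bundles a read identifier, its base string over
#' `{A,C,G,T,N}` and the per-base PHRED quality scores. It is the unit all
#' inference functions in this package operate on.
#'
#' @param id Character scalar, the read identifier.
#' @param bases Character scalar, base calls over `{A,C,G,T,N}`
#'   (lower case accepted, stored upper case).
#' @param quals Integer vector of PHRED quality scores, one per base,
#'   all `>= 0`.
#'
#' @return An object of class `read_record`: a list with elements `id`,
#'   `bases` and `quals`.
#' @examples
#' read_record("r1", "ACGT", c(30, 30, 30, 30))
#' @export
read_record <- function(id, bases, quals) {
  if (!is.character(id) || length(id) != 1L || is.na(id)) {
    stop("'id' must be a single character string")
  }
  if (!is.character(bases) || length(bases) != 1L || is.na(bases)) {
    stop("'bases' must be a single character string")
  }
  bases <- toupper(bases)
  if (!grepl("^[ACGTN]*$", bases)) {
    stop("read '", id, "': bases must be over {A,C,G,T,N}")
  }
  quals <- as.integer(quals)
  if (length(quals) != nchar(bases)) {
    stop("read '", id, "': quality vector length (", length(quals),
         ") != number of bases (", nchar(bases), ")")
  }
  if (anyNA(quals) || any(quals < 0L)) {
    stop("read '", id, "': quality scores must be non-negative integers")
  }
  structure(list(id = id, bases = bases, quals = quals),
            class = "read_record")
}

#' @export
print.read_record <- function(x, ...) {
  cat("<read_record> ", x$id, "\n", sep = "")
  cat("  bases: ", .abbrev_seq(x$bases), " (", nchar(x$bases), " bp)\n",
      sep = "")
  cat("  quals: ", .abbrev_seq(paste(x$quals, collapse = " ")), "\n",
      sep = "")
  invisible(x)
}

#' @export
length.read_record <- function(x) nchar(x$bases)

.abbrev_seq <- function(s, n = 60L) {
  if (nchar(s) > n) paste0(substr(s, 1L, n), "...") else s
}

## reverse complement of a plain base string vector (N stays N)
.revcomp_chr <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Reverse complement a read
#'
#' Complements the base string (`N` maps to `N`), reverses it, and reverses
#' the quality vector so that qualities keep tracking their bases. Used to
#' place read 2 on the same strand as read 1 before overlap scoring.
#'
#' @param read A [read_record()].
#' @return A `read_record` with complemented, reversed bases and reversed
#'   qualities.
#' @examples
#' reverse_complement(read_record("r", "AACG", c(10, 20, 30, 40)))
#' @export
reverse_complement <- function(read) {
  stopifnot(inherits(read, "read_record"))
  read_record(read$id, .revcomp_chr(read$bases), rev(read$quals))
}

## split a base string into a character vector of single bases
.chars <- function(s) {
  if (nchar(s) == 0L) character(0) else strsplit(s, "", fixed = TRUE)[[1L]]
}
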