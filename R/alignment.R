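#' In-frame codon alignment
#'
#' A light container for an in-frame coding nucleotide alignment: a named set
#' of equal-length sequences over `{A,C,G,T,-,N}` plus a reading-frame offset
#' (0-based column index of codon position 1). Codon-aware operations require
#' `(length - offset)` to be divisible by 3.
#'
#' @param seqs named character vector of aligned sequences (upper or lower
#'   case; normalised to upper).
#' @param offset 0-based column index where codon position 1 starts.
#' @return an object of class `"codon_alignment"`.
#' @export
codon_alignment <- function(seqs, offset = 0L) {
  if (length(seqs) == 0L) stop("empty alignment")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  if (anyDuplicated(names(seqs))) stop("duplicate taxon labels")
  seqs <- toupper(seqs)
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop("ragged alignment: sequence lengths ", paste(nchar(seqs), collapse = ", "))
  if (len == 0L) stop("zero-length alignment")
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("invalid characters in sequences: ", paste(names(seqs)[bad], collapse = ", "))
  offset <- as.integer(offset)
  if (offset < 0L || offset >= len) stop("offset out of range")
  structure(list(seqs = seqs, length = len, offset = offset),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment:", length(x$seqs), "sequences x", x$length,
      "columns (frame offset", x$offset, ")\n")
  invisible(x)
}

#' Number of columns of an alignment
#' @param aln a `"codon_alignment"`.
#' @export
aln_length <- function(aln) aln$length

#' Taxon labels of an alignment
#' @param aln a `"codon_alignment"`.
#' @export
aln_taxa <- function(aln) names(aln$seqs)

#' Alignment as a character matrix (rows = taxa, columns = sites)
#' @param x a `"codon_alignment"`.
#' @param ... unused.
#' @export
as.matrix.codon_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(unname(x$seqs), ""))
  rownames(m) <- names(x$seqs)
  m
}

#' Read a FASTA alignment
#'
#' Reads an aligned FASTA (string or file path) into a [codon_alignment()].
#' Records must be equal length; case is normalised to upper.
#'
#' @param x FASTA text or path of a FASTA file.
#' @param offset reading-frame offset, see [codon_alignment()].
#' @return a `"codon_alignment"`.
#' @export
read_fasta <- function(x, offset = 0L) {
  stopifnot(is.character(x), length(x) == 1L)
  lines <- if (file.exists(x) && !startsWith(trimws(x), ">")) {
    readLines(x, warn = FALSE)
  } else strsplit(x, "\n", fixed = TRUE)[[1L]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty FASTA input")
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("FASTA must start with a '>' header")
  idx <- cumsum(hdr)
  nm <- sub("^>\\s*", "", lines[hdr])
  nm <- sub("\\s.*$", "", nm)             # first whitespace-delimited token
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 paste, character(1L), collapse = "")
  if (length(seqs) != length(nm)) stop("FASTA record without sequence")
  names(seqs) <- nm
  codon_alignment(seqs, offset = offset)
}

#' Write an alignment as FASTA
#' @param aln a `"codon_alignment"`.
#' @param file output path; `NULL` returns the text.
#' @param width sequence line width.
#' @export
write_fasta <- function(aln, file = NULL, width = 70L) {
  stopifnot(inherits(aln, "codon_alignment"))
  out <- unlist(lapply(names(aln$seqs), function(nm) {
    s <- aln$seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", nm), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  paste(out, collapse = "\n")
}

#' Filter alignment columns by codon position
#'
#' Keeps the columns belonging to the requested codon positions (subset of
#' `{1, 2, 3}`), e.g. `keep = c(1, 2)` drops the fast-evolving third
#' position. Any out-of-frame prefix columns (before `offset`) are dropped.
#' The returned alignment has offset 0; its codon structure is preserved only
#' when all three positions are kept.
#'
#' @param aln an in-frame `"codon_alignment"` (`(length - offset) %% 3 == 0`).
#' @param keep integer subset of `1:3`.
#' @return a `"codon_alignment"` with the filtered columns.
#' @export
codon_partition <- function(aln, keep = 1:3) {
  stopifnot(inherits(aln, "codon_alignment"))
  keep <- sort(unique(as.integer(keep)))
  if (length(keep) == 0L || any(!keep %in% 1:3))
    stop("'keep' must be a non-empty subset of 1:3")
  ncod <- aln$length - aln$offset
  if (ncod %% 3L != 0L)
    stop("frame violation: length - offset = ", ncod, " is not divisible by 3")
  pos <- rep(1:3, ncod / 3L)
  cols <- aln$offset + which(pos %in% keep)
  seqs <- vapply(aln$seqs, function(s)
    paste(strsplit(s, "")[[1L]][cols], collapse = ""), character(1L))
  codon_alignment(seqs, offset = 0L)
}
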