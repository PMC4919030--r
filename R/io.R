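#' Read and write protein FASTA
#'
#' Thin wrappers around [Biostrings::readAAStringSet()] returning plain named
#' character vectors, the representation the rest of the package works with.
#' Output is wrapped at 60 columns.
#'
#' @param path file path.
#' @param seqs named character vector of amino-acid sequences.
#' @return `read_fasta()`: a named character vector; `write_fasta()`: the
#'   path, invisibly.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  ss <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read and write multiple alignments
#'
#' Alignments are named character vectors of equal-length gapped sequences
#' (`-` for gaps). Aligned FASTA is the default interchange format; a minimal
#' Stockholm reader/writer is provided for profile-HMM seed alignments.
#'
#' @param aln named character vector, all elements the same nchar.
#' @param path file path.
#' @return the alignment (readers) or the path, invisibly (writers).
#' @export
read_alignment <- function(path) {
  aln <- read_fasta(path)
  if (length(unique(nchar(aln))) != 1L)
    stop("aligned FASTA rows have unequal lengths", call. = FALSE)
  aln
}

#' @rdname read_alignment
#' @export
write_alignment <- function(aln, path) {
  check_alignment(aln)
  write_fasta(aln, path)
}

#' @rdname read_alignment
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & !grepl("^//", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("no sequence lines in Stockholm file", call. = FALSE)
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  ids <- vapply(parts, `[[`, "", 1L)
  seq <- vapply(parts, `[[`, "", 2L)
  aln <- vapply(split(seq, factor(ids, levels = unique(ids))),
                paste0, "", collapse = "")
  aln <- chartr(".", "-", aln)
  if (length(unique(nchar(aln))) != 1L)
    stop("Stockholm rows have unequal lengths", call. = FALSE)
  aln
}

#' @rdname read_alignment
#' @export
write_stockholm <- function(aln, path) {
  check_alignment(aln)
  w <- max(nchar(names(aln))) + 2L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# STOCKHOLM 1.0", con)
  writeLines(sprintf("%-*s%s", w, names(aln), aln), con)
  writeLines("//", con)
  invisible(path)
}

check_alignment <- function(aln) {
  stopifnot(is.character(aln), !is.null(names(aln)), length(aln) >= 1L)
  if (length(unique(nchar(aln))) != 1L)
    stop("alignment rows have unequal lengths", call. = FALSE)
  invisible(aln)
}

# drop gaps from one alignment row
ungap <- function(x) gsub("-", "", x, fixed = TRUE)
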