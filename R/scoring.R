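#' Scoring schemes for local alignment
#'
#' A scoring scheme bundles a symmetric integer substitution matrix with
#' affine gap penalties in the FASTA/PRSS convention: a gap of length k costs
#' `|gap_open| + k * |gap_extend|`. The survey's reference scheme is BLOSUM50
#' with gap open -10 and gap extend -2. Residue `X` scores 0 against
#' everything.
#'
#' @param matrix_name name of a packaged matrix (`"BLOSUM50"`) or path to a
#'   matrix file in NCBI text format.
#' @param gap_open gap opening penalty, negative.
#' @param gap_extend gap extension penalty, negative.
#' @return an object of class `scoring_scheme`: list with `matrix_name`,
#'   `matrix` (24 x 24 integer, rows/cols named), `gap_open`, `gap_extend`,
#'   `alphabet`.
#' @examples
#' sc <- scoring_scheme()
#' sc$matrix["H", "H"]
#' @export
scoring_scheme <- function(matrix_name = "BLOSUM50", gap_open = -10L,
                           gap_extend = -2L) {
  if (!(gap_open < 0 && gap_extend < 0))
    stop("gap_open and gap_extend must be negative", call. = FALSE)
  path <- if (file.exists(matrix_name)) matrix_name else
    system.file("extdata", paste0(matrix_name, ".txt"), package = "hrsurvey")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown scoring matrix: ", matrix_name, call. = FALSE)
  m <- read_score_matrix(path)
  # X is the unknown-residue wildcard: neutral against everything
  if ("X" %in% rownames(m)) { m["X", ] <- 0L; m[, "X"] <- 0L }
  structure(list(matrix_name = matrix_name, matrix = m,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 alphabet = rownames(m)),
            class = "scoring_scheme")
}

#' Read a substitution matrix in NCBI text format
#'
#' @param path path to a whitespace-separated matrix file with a header row of
#'   residue letters and one labelled row per residue; `#` lines are comments.
#' @return symmetric integer matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[[1]]), "[[:space:]]+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "[[:space:]]+")
  lab <- vapply(rows, `[[`, "", 1L)
  vals <- t(vapply(rows, function(r) as.integer(r[-1]), integer(length(header))))
  dimnames(vals) <- list(lab, header)
  if (!identical(rownames(vals), colnames(vals)))
    stop("matrix rows and columns disagree", call. = FALSE)
  if (!isTRUE(all.equal(vals, t(vals))))
    stop("substitution matrix is not symmetric", call. = FALSE)
  vals
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("Scoring scheme:", x$matrix_name,
      sprintf("(gap open %d, gap extend %d)\n", x$gap_open, x$gap_extend))
  invisible(x)
}
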