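#' K-mer distance matrix
#'
#' `d(x, y) = 1 - |K(x) intersect K(y)| / min(|K(x)|, |K(y)|)` over the sets
#' of distinct k-mers of each sequence (min-normalized shared-kmer
#' fraction). `d(x, x) = 0`; a sequence shorter than `k` has no k-mers and
#' sits at distance 1 from everything.
#'
#' @param seqs named character vector of sequences.
#' @param k word length (>= 1, default 3).
#' @return symmetric numeric matrix with zero diagonal and the sequence
#'   names as dimnames.
#' @export
kmer_distance <- function(seqs, k = 3L) {
  stopifnot(k >= 1L, !is.null(names(seqs)))
  n <- length(seqs)
  km <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, 1:(L - k + 1L), k:L))
  })
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    ni <- length(km[[i]]); nj <- length(km[[j]])
    d[i, j] <- d[j, i] <- if (ni == 0L || nj == 0L) 1 else
      1 - length(intersect(km[[i]], km[[j]])) / min(ni, nj)
  }
  d
}

#' UPGMA guide tree
#'
#' Average-linkage agglomerative clustering of a distance matrix (the
#' standard UPGMA merge rule, delegated to [stats::hclust()]), returned as a
#' merge schedule for the progressive aligner plus an ultrametric
#' `ape::phylo` rendering. Ties are broken deterministically by label order.
#'
#' @param dm symmetric distance matrix with labels.
#' @return object of class `guide_tree`: list with `merge` (hclust merge
#'   matrix), `height`, `labels`, `phylo`.
#' @export
guide_tree <- function(dm) {
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-12)))
    stop("distance matrix must be symmetric", call. = FALSE)
  stopifnot(nrow(dm) >= 2L)
  hc <- hclust(as.dist(dm), method = "average")
  structure(list(merge = hc$merge, height = hc$height, labels = hc$labels,
                 phylo = ape::as.phylo(hc)),
            class = "guide_tree")
}

#' @export
print.guide_tree <- function(x, ...) {
  cat(sprintf("UPGMA guide tree over %d sequences (root height %.4g)\n",
              length(x$labels), max(x$height) / 2))
  invisible(x)
}

#' Progressive multiple alignment
#'
#' Aligns sequences bottom-up along a UPGMA guide tree by global
#' profile-profile alignment with affine gaps. Profile columns are scored by
#' the average-of-pairs substitution score; a residue against a gap scores
#' the gap-extension penalty and gap against gap scores 0; once a gap is
#' introduced into a merged profile it is never removed ("once a gap, always
#' a gap").
#'
#' @param seqs named character vector of unaligned sequences.
#' @param scheme a [scoring_scheme()].
#' @param guide optional [guide_tree()]; defaults to UPGMA on
#'   [kmer_distance()].
#' @return named character vector: the aligned rows (equal length, `-` for
#'   gaps), in input order.
#' @export
progressive_align <- function(seqs, scheme = scoring_scheme(), guide = NULL) {
  stopifnot(!is.null(names(seqs)), length(seqs) >= 1L)
  if (length(seqs) == 1L) return(seqs)
  if (is.null(guide)) guide <- guide_tree(kmer_distance(seqs))
  if (!setequal(guide$labels, names(seqs)))
    stop("guide tree leaves do not match sequence ids", call. = FALSE)
  A <- scheme$alphabet[seq_len(20L)]
  prof_of_rows <- function(rows) {
    mat <- do.call(rbind, strsplit(rows, ""))
    counts <- matrix(0, ncol(mat), 21L)
    for (r in seq_len(20L)) counts[, r] <- colSums(mat == A[r])
    counts[, 21L] <- colSums(mat == "-")
    # X and other wildcards count as nothing (neither residue nor gap)
    counts
  }
  merge_rows <- function(rowsA, rowsB, path) {
    outA <- character(length(rowsA)); outB <- character(length(rowsB))
    chA <- strsplit(rowsA, ""); chB <- strsplit(rowsB, "")
    gapA <- path != 3L; gapB <- path != 2L  # which output cols consume A / B
    nc <- length(path)
    build <- function(ch, use) {
      out <- rep("-", nc)
      out[use] <- ch
      paste(out, collapse = "")
    }
    useA <- which(path %in% c(1L, 2L)); useB <- which(path %in% c(1L, 3L))
    c(vapply(chA, build, "", use = useA), vapply(chB, build, "", use = useB))
  }
  sub20 <- scheme$matrix[A, A]
  # walk the hclust merge schedule
  cluster_rows <- vector("list", nrow(guide$merge))
  get_rows <- function(idx) {
    if (idx < 0) setNames(seqs[guide$labels[-idx]], guide$labels[-idx])
    else cluster_rows[[idx]]
  }
  for (i in seq_len(nrow(guide$merge))) {
    ra <- get_rows(guide$merge[i, 1L])
    rb <- get_rows(guide$merge[i, 2L])
    path <- .profile_align(prof_of_rows(ra), prof_of_rows(rb), sub20,
                           -scheme$gap_open, -scheme$gap_extend)
    merged <- merge_rows(ra, rb, path)
    names(merged) <- c(names(ra), names(rb))
    cluster_rows[[i]] <- merged
  }
  out <- cluster_rows[[nrow(guide$merge)]]
  out[names(seqs)]
}

#' Average-of-pairs alignment score
#'
#' Mean over all row pairs of the summed column scores (residue-residue from
#' the substitution matrix, residue-gap = gap extension, gap-gap = 0). Used
#' to compare alignments of the same sequences.
#'
#' @param aln named character vector alignment.
#' @param scheme a [scoring_scheme()].
#' @return numeric scalar.
#' @export
sum_of_pairs_score <- function(aln, scheme = scoring_scheme()) {
  check_alignment(aln)
  mat <- do.call(rbind, strsplit(aln, ""))
  n <- nrow(mat)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- mat[i, ]; b <- mat[j, ]
    both <- a != "-" & b != "-"
    one <- xor(a == "-", b == "-")
    tot <- tot + sum(scheme$matrix[cbind(a[both], b[both])]) +
      sum(one) * scheme$gap_extend
  }
  tot / (n * (n - 1) / 2)
}
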