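#' Smith-Waterman local alignment
#'
#' Optimal local alignment with affine gaps under a [scoring_scheme()].
#' Traceback tie-breaks are fixed for reproducibility: diagonal over
#' subject-gap over query-gap, and among equal-scoring end cells the smallest
#' (query end, subject end) pair. Intervals are 1-based closed; an empty
#' input yields an empty alignment with score 0.
#'
#' @param query,subject amino-acid strings (standard 20 letters plus `X`,
#'   which scores 0 against everything).
#' @param scheme a [scoring_scheme()].
#' @param identity_denominator `"columns"` (all aligned columns, including
#'   gap columns; the FASTA-suite convention) or `"matched"` (residue-residue
#'   columns only).
#' @return object of class `local_alignment`: list with `score`,
#'   `query_interval`, `subject_interval` (1-based closed, integer length 2),
#'   `column_states` (character: match/mismatch/query-gap/subject-gap),
#'   `identity_percent`, `overlap_length`.
#' @examples
#' sw <- smith_waterman("HHE", "HHE")
#' sw$score # 26 = 10 + 10 + 6 on the BLOSUM50 diagonal
#' @export
smith_waterman <- function(query, subject, scheme = scoring_scheme(),
                           identity_denominator = c("columns", "matched")) {
  identity_denominator <- match.arg(identity_denominator)
  if (nchar(query) == 0L || nchar(subject) == 0L) {
    return(structure(list(score = 0L,
                          query_interval = c(1L, 0L),
                          subject_interval = c(1L, 0L),
                          column_states = character(0),
                          identity_percent = NA_real_,
                          overlap_length = 0L),
                     class = "local_alignment"))
  }
  qi <- aa_encode(query, scheme$alphabet, extra = character(0)) - 1L
  si <- aa_encode(subject, scheme$alphabet, extra = character(0)) - 1L
  res <- .sw_align(qi, si, scheme$matrix, -scheme$gap_open, -scheme$gap_extend)
  st <- c("match", "mismatch", "query-gap", "subject-gap")[res$states + 1L]
  ncol_aln <- length(st)
  nmatch <- sum(st == "match")
  denom <- if (identity_denominator == "columns") ncol_aln else
    sum(st %in% c("match", "mismatch"))
  structure(list(score = res$score,
                 query_interval = c(res$q_start, res$q_end),
                 subject_interval = c(res$s_start, res$s_end),
                 column_states = st,
                 identity_percent = if (ncol_aln) 100 * nmatch / denom else NA_real_,
                 overlap_length = ncol_aln),
            class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("Local alignment: score %d, overlap %d, identity %.1f%%\n",
              x$score, x$overlap_length,
              if (is.na(x$identity_percent)) NA else x$identity_percent))
  cat(sprintf("  query %d..%d  subject %d..%d\n",
              x$query_interval[1], x$query_interval[2],
              x$subject_interval[1], x$subject_interval[2]))
  invisible(x)
}

#' Moment fit of the Gumbel (type-I extreme value) distribution
#'
#' Location/scale fit by the method of moments:
#' `lambda = pi / (sd * sqrt(6))`, `mu = mean - gamma_Euler / lambda`.
#' The upper tail probability at `s` is
#' `1 - exp(-exp(-lambda * (s - mu)))`.
#'
#' @param scores numeric sample.
#' @return list with `mu`, `lambda`.
#' @export
fit_gumbel <- function(scores) {
  s <- sd(scores)
  if (!is.finite(s) || s == 0)
    stop("degenerate null: shuffle/background scores have zero variance",
         call. = FALSE)
  lambda <- pi / (s * sqrt(6))
  mu <- mean(scores) - 0.577215664901533 / lambda
  list(mu = mu, lambda = lambda)
}

gumbel_upper_tail <- function(s, mu, lambda) {
  # numerically safe 1 - exp(-exp(-x)); -expm1 keeps precision in the far tail
  -expm1(-exp(-lambda * (s - mu)))
}

#' PRSS-style shuffle significance of a local alignment
#'
#' The subject is uniformly permuted (Fisher-Yates, via `sample()`)
#' `n_shuffles` times and re-aligned against the query; a Gumbel distribution
#' is fitted to the shuffle scores by the method of moments and the observed
#' score converted to a p-value. The expect value uses the single-comparison
#' convention `expect = p_value`; `p_times_n = p_value * n_shuffles` is also
#' reported.
#'
#' @inheritParams smith_waterman
#' @param n_shuffles number of subject permutations (at least 10; the survey
#'   default is 200).
#' @param seed integer seed governing the permutation stream.
#' @return object of class `shuffle_sig`: list with `n_shuffles`,
#'   `observed_score`, `shuffle_scores`, `gumbel_mu`, `gumbel_lambda`,
#'   `p_value`, `expect`, `p_times_n`.
#' @export
shuffle_significance <- function(query, subject, scheme = scoring_scheme(),
                                 n_shuffles = 200L, seed = 1L) {
  if (n_shuffles < 10L)
    stop("n_shuffles must be at least 10", call. = FALSE)
  qi <- aa_encode(query, scheme$alphabet, extra = character(0)) - 1L
  si <- aa_encode(subject, scheme$alphabet, extra = character(0)) - 1L
  go <- -scheme$gap_open; ge <- -scheme$gap_extend
  obs <- .sw_score(qi, si, scheme$matrix, go, ge)
  scores <- withr::with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i)
      .sw_score(qi, sample(si), scheme$matrix, go, ge), integer(1))
  })
  fit <- fit_gumbel(scores)  # errors on zero variance (degenerate null)
  p <- gumbel_upper_tail(obs, fit$mu, fit$lambda)
  structure(list(n_shuffles = as.integer(n_shuffles),
                 observed_score = obs,
                 shuffle_scores = scores,
                 gumbel_mu = fit$mu, gumbel_lambda = fit$lambda,
                 p_value = p, expect = p, p_times_n = p * n_shuffles),
            class = "shuffle_sig")
}

#' @export
print.shuffle_sig <- function(x, ...) {
  cat(sprintf("Shuffle significance: score %d vs %d shuffles\n",
              x$observed_score, x$n_shuffles))
  cat(sprintf("  Gumbel mu %.2f lambda %.4f  E() %.3g\n",
              x$gumbel_mu, x$gumbel_lambda, x$expect))
  invisible(x)
}

#' Homology decision at the survey cutoff
#'
#' A pair is called homologous when the expect value is strictly below the
#' threshold (default 1e-3, the survey's cutoff); an expect exactly at the
#' threshold is not a homolog.
#'
#' @param sig a `shuffle_sig` object (or anything with an `expect` field).
#' @param threshold expect-value cutoff.
#' @return logical.
#' @export
is_homolog <- function(sig, threshold = 1e-3) {
  isTRUE(sig$expect < threshold)
}

#' Pairwise identity table for a set of reference chains
#'
#' Aligns every ordered pair of sequences and reports percent identity and
#' shuffle-based significance — the layout used to justify seed queries. The
#' PDB chain sequences themselves are user-supplied (a one-time download);
#' the packaged pipeline never fetches them.
#'
#' @param seqs named character vector of protein sequences.
#' @param scheme a [scoring_scheme()].
#' @param n_shuffles,seed passed to [shuffle_significance()].
#' @param shuffles if `FALSE`, skip significance and report identities only.
#' @return data.frame: query, subject, score, identity_percent, overlap,
#'   expect.
#' @export
pairwise_identity_table <- function(seqs, scheme = scoring_scheme(),
                                    n_shuffles = 200L, seed = 1L,
                                    shuffles = TRUE) {
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  pairs <- expand.grid(q = names(seqs), s = names(seqs),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$q != pairs$s, ]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    qn <- pairs$q[i]; sn <- pairs$s[i]
    al <- smith_waterman(seqs[[qn]], seqs[[sn]], scheme)
    ev <- if (shuffles)
      shuffle_significance(seqs[[qn]], seqs[[sn]], scheme,
                           n_shuffles = n_shuffles,
                           seed = derive_seed(seed, i))$expect
    else NA_real_
    data.frame(query = qn, subject = sn, score = al$score,
               identity_percent = al$identity_percent,
               overlap = al$overlap_length, expect = ev,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
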