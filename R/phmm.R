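#' Build a profile HMM from a seed alignment
#'
#' Alignment columns whose non-gap occupancy is at least `match_rule` become
#' match nodes; the rest are insert columns. Match emissions are Laplace-
#' smoothed counts; at anchor columns the count of the stated residue is
#' multiplied by the anchor weight before smoothing, encoding the
#' hand-curated up-weighting of the iron-coordinating positions. Transitions
#' are counted from the observed per-row state paths with pseudocount 1 per
#' transition type. Insert emissions equal the background (LG equilibrium)
#' frequencies.
#'
#' @param msa named character vector: the seed alignment.
#' @param match_rule occupancy threshold for a column to become a match node
#'   (default 0.5).
#' @param pseudocount Laplace smoothing constant (default 1).
#' @param anchors optional data.frame with columns `column` (alignment
#'   column, 1-based), `residue`, `weight` (default weight 5).
#' @param profile_id label for the model.
#' @return object of class `profile_hmm`: list with `profile_id`,
#'   `node_count`, `match_emissions` (node_count x 20), `insert_emissions`
#'   ((node_count + 1) x 20), `transitions` (node_count x 7, columns
#'   MM MI MD IM II DM DD), `background`, `anchor_nodes`, `match_columns`.
#' @export
build_phmm <- function(msa, match_rule = 0.5, pseudocount = 1.0,
                       anchors = NULL, profile_id = "profile") {
  check_alignment(msa)
  if (length(msa) < 2L) stop("seed alignment needs >= 2 rows", call. = FALSE)
  mat <- do.call(rbind, strsplit(msa, ""))
  L <- ncol(mat); nrow_ <- nrow(mat)
  occ <- colMeans(mat != "-")
  is_match <- occ >= match_rule
  M <- sum(is_match)
  if (M == 0L) stop("empty model: no column reaches the occupancy threshold",
                    call. = FALSE)
  node_of_col <- cumsum(is_match)           # column -> node index (match cols)
  bg <- as.numeric(lg_model()$frequencies)
  # --- match emissions
  em <- matrix(0, M, 20L, dimnames = list(NULL, AA20))
  mc <- which(is_match)
  for (k in seq_len(M)) {
    cnt <- table(factor(mat[, mc[k]], levels = AA20))
    em[k, ] <- as.numeric(cnt)
  }
  anchor_nodes <- NULL
  if (!is.null(anchors) && nrow(anchors)) {
    if (is.null(anchors$weight)) anchors$weight <- 5.0
    keep <- anchors$column %in% mc
    a <- anchors[keep, , drop = FALSE]
    if (nrow(a)) {
      a$node <- node_of_col[a$column]
      for (i in seq_len(nrow(a)))
        em[a$node[i], a$residue[i]] <- em[a$node[i], a$residue[i]] * a$weight[i]
      anchor_nodes <- data.frame(node = a$node, residue = a$residue,
                                 weight = a$weight, stringsAsFactors = FALSE)
    }
  }
  em <- em + pseudocount
  em <- em / rowSums(em)
  # --- transitions from observed state paths
  trn <- matrix(pseudocount, M, 7L,
                dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  for (r in seq_len(nrow_)) {
    prev_state <- NULL; prev_node <- 0L
    for (j in seq_len(L)) {
      st <- if (is_match[j]) { if (mat[r, j] == "-") "D" else "M" }
            else { if (mat[r, j] == "-") NA else "I" }
      if (is.na(st)) next
      node <- if (is_match[j]) node_of_col[j] else node_of_col[j]  # I_k after node k
      if (!is.null(prev_state)) {
        from_node <- prev_node
        key <- paste0(prev_state, st)
        if (key %in% colnames(trn) && from_node >= 1L && from_node <= M)
          trn[from_node, key] <- trn[from_node, key] + 1
      }
      prev_state <- st; prev_node <- node
    }
  }
  # normalize per group
  for (grp in list(c("MM", "MI", "MD"), c("IM", "II"), c("DM", "DD")))
    trn[, grp] <- trn[, grp, drop = FALSE] /
      rowSums(trn[, grp, drop = FALSE])
  ins <- matrix(rep(bg, each = M + 1L), M + 1L, 20L,
                dimnames = list(NULL, AA20))
  structure(list(profile_id = profile_id, node_count = M,
                 match_emissions = em, insert_emissions = ins,
                 transitions = trn, background = setNames(bg, AA20),
                 anchor_nodes = anchor_nodes, match_columns = mc),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("Profile HMM '%s': %d nodes, %d anchors\n", x$profile_id,
              x$node_count,
              if (is.null(x$anchor_nodes)) 0L else nrow(x$anchor_nodes)))
  invisible(x)
}

# log2-odds pieces shared by viterbi/forward; appends a 21st emission column
# for X (log-odds 0: uninformative residue)
phmm_log_parts <- function(model) {
  lm <- log2(model$match_emissions) - rep(log2(model$background),
                                          each = model$node_count)
  M <- model$node_count
  li <- matrix(0, max(M - 1L, 1L), 20L)
  if (M > 1L)
    li <- log2(model$insert_emissions[2:M, , drop = FALSE]) -
      rep(log2(model$background), each = M - 1L)
  lm <- cbind(lm, 0)            # X column
  li <- cbind(li, 0)
  tr <- log2(model$transitions)
  list(lm = lm, li = rbind(li, 0), tr = tr)
}

#' Scan a protein with a profile HMM (local Viterbi)
#'
#' Returns the best-scoring local match in log2-odds bits:
#' `max over paths of log2 P(path, residues | model) - log2 P(residues |
#' background)`, with uniform local entry/exit over match nodes. With
#' `multihit = TRUE`, further non-overlapping envelopes are reported while
#' their score stays at or above `floor`.
#'
#' @param model a [build_phmm()] or [read_phmm()] model.
#' @param protein amino-acid string (or named character vector of length 1).
#' @param floor reporting floor in bits (default 0): weaker hits return
#'   `NULL` (single-hit) or are dropped (multi-hit).
#' @param multihit report multiple non-overlapping envelopes.
#' @param protein_id label carried into the hit.
#' @return a `domain_hit` (list with `protein_id`, `profile_id`,
#'   `bit_score`, `query_envelope`, `profile_span` — both 1-based closed —
#'   `reference_coverage`, `protein_coverage`), or a list of them
#'   (`multihit = TRUE`), or `NULL` when nothing reaches the floor.
#' @export
viterbi_scan <- function(model, protein, floor = 0, multihit = FALSE,
                         protein_id = names(protein) %||% "protein") {
  protein <- unname(protein)
  parts <- phmm_log_parts(model)
  x <- aa_encode(protein, extra = "X") - 1L  # X -> code 20 (21st column)
  one_hit <- function(codes, offset) {
    if (!length(codes)) return(NULL)
    v <- .phmm_viterbi(parts$lm, parts$li, parts$tr, codes)
    if (is.na(v$score) || v$score < floor) return(NULL)
    env <- c(v$env_start, v$env_end) + offset
    span <- c(v$node_start, v$node_end)
    structure(list(protein_id = protein_id, profile_id = model$profile_id,
                   bit_score = v$score, evalue = NA_real_,
                   query_envelope = env, profile_span = span,
                   reference_coverage = (span[2] - span[1] + 1) / model$node_count,
                   protein_coverage = (env[2] - env[1] + 1) / nchar(protein)),
              class = "domain_hit")
  }
  if (!multihit) return(one_hit(x, 0L))
  # iteratively mask found envelopes and rescan the flanks
  hits <- list()
  segments <- list(c(1L, length(x)))
  while (length(segments)) {
    seg <- segments[[1]]; segments <- segments[-1]
    if (seg[2] - seg[1] + 1L < 5L) next
    h <- one_hit(x[seg[1]:seg[2]], seg[1] - 1L)
    if (is.null(h)) next
    hits[[length(hits) + 1L]] <- h
    e <- h$query_envelope
    if (e[1] - 1L >= seg[1]) segments <- c(segments, list(c(seg[1], e[1] - 1L)))
    if (e[2] + 1L <= seg[2]) segments <- c(segments, list(c(e[2] + 1L, seg[2])))
  }
  if (!length(hits)) return(NULL)
  hits[order(vapply(hits, function(h) h$query_envelope[1], 1))]
}

#' @export
print.domain_hit <- function(x, ...) {
  cat(sprintf("Domain hit %s ~ %s: %.1f bits, env %d..%d, nodes %d..%d%s\n",
              x$protein_id, x$profile_id, x$bit_score,
              x$query_envelope[1], x$query_envelope[2],
              x$profile_span[1], x$profile_span[2],
              if (is.na(x$evalue)) "" else sprintf(", E = %.3g", x$evalue)))
  invisible(x)
}

#' Forward bit score of a protein under a profile HMM
#'
#' Log-sum over all local paths with the same entry/exit and null model as
#' [viterbi_scan()]; always at least the Viterbi score.
#'
#' @inheritParams viterbi_scan
#' @return numeric bit score.
#' @export
forward_score <- function(model, protein) {
  parts <- phmm_log_parts(model)
  x <- aa_encode(unname(protein), extra = "X") - 1L
  .phmm_forward(parts$lm, parts$li, parts$tr, x)
}

#' Calibrate an E-value null for a profile HMM
#'
#' Viterbi bit scores of `n_random` background sequences (LG equilibrium
#' frequencies) of the given length are fitted with a Gumbel distribution by
#' the method of moments; [evalue()] then converts a bit score to an
#' expectation over a database of a given size.
#'
#' @param model a profile HMM.
#' @param n_random number of background sequences (>= 100, default 1000).
#' @param length background sequence length (default: model length).
#' @param seed integer seed.
#' @return object of class `evalue_calibration`: list with `profile_id`,
#'   `n_random`, `length`, `gumbel_mu`, `gumbel_lambda`.
#' @export
calibrate_evalue <- function(model, n_random = 1000L, length = NULL,
                             seed = 1L) {
  if (n_random < 100L) stop("n_random must be >= 100", call. = FALSE)
  L <- as.integer(length %||% model$node_count)
  parts <- phmm_log_parts(model)
  bg <- model$background
  scores <- withr::with_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      x <- sample.int(20L, L, replace = TRUE, prob = bg) - 1L
      .phmm_viterbi(parts$lm, parts$li, parts$tr, x)$score
    }, 1)
  })
  fit <- fit_gumbel(scores)  # degenerate-null error on zero variance
  structure(list(profile_id = model$profile_id, n_random = as.integer(n_random),
                 length = L, gumbel_mu = fit$mu, gumbel_lambda = fit$lambda),
            class = "evalue_calibration")
}

#' @rdname calibrate_evalue
#' @param calibration an `evalue_calibration`.
#' @param bit_score Viterbi bit score(s).
#' @param database_size number of sequences searched.
#' @return `evalue()`: expected number of equal-or-better chance hits.
#' @export
evalue <- function(calibration, bit_score, database_size = 1L) {
  database_size *
    gumbel_upper_tail(bit_score, calibration$gumbel_mu,
                      calibration$gumbel_lambda)
}

#' Scan a whole proteome and tabulate domain hits
#'
#' Runs [viterbi_scan()] over every protein, attaches calibrated E-values,
#' and keeps hits with `evalue < evalue_cutoff` and `bit_score > floor`.
#'
#' @param model a profile HMM.
#' @param proteins named character vector (or `synthetic_proteome`).
#' @param calibration an [calibrate_evalue()] result; computed on the fly
#'   when `NULL`.
#' @param evalue_cutoff reporting threshold (default 1e-3).
#' @param floor bit-score floor (default 0).
#' @param multihit allow several envelopes per protein.
#' @param database_size E-value scaling; defaults to the proteome size.
#' @return data.frame (one row per hit): protein_id, profile_id, bit_score,
#'   evalue, env_start, env_end, profile_start, profile_end,
#'   reference_coverage, protein_coverage, classification.
#' @export
scan_proteome <- function(model, proteins, calibration = NULL,
                          evalue_cutoff = 1e-3, floor = 0, multihit = FALSE,
                          database_size = NULL) {
  if (inherits(proteins, "synthetic_proteome")) proteins <- proteins$proteins
  n_db <- database_size %||% length(proteins)
  if (is.null(calibration))
    calibration <- calibrate_evalue(model, length = max(nchar(proteins)))
  rows <- list()
  for (id in names(proteins)) {
    hs <- viterbi_scan(model, proteins[[id]], floor = floor,
                       multihit = multihit, protein_id = id)
    if (is.null(hs)) next
    if (!multihit) hs <- list(hs)
    for (h in hs) {
      ev <- evalue(calibration, h$bit_score, n_db)
      if (ev >= evalue_cutoff) next
      rows[[length(rows) + 1L]] <-
        data.frame(protein_id = id, profile_id = h$profile_id,
                   bit_score = h$bit_score, evalue = ev,
                   env_start = h$query_envelope[1], env_end = h$query_envelope[2],
                   profile_start = h$profile_span[1],
                   profile_end = h$profile_span[2],
                   reference_coverage = h$reference_coverage,
                   protein_coverage = h$protein_coverage,
                   classification = classify_coverage(h),
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(protein_id = character(0), profile_id = character(0),
                      bit_score = numeric(0), evalue = numeric(0),
                      env_start = integer(0), env_end = integer(0),
                      profile_start = integer(0), profile_end = integer(0),
                      reference_coverage = numeric(0),
                      protein_coverage = numeric(0),
                      classification = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Single-domain versus long classification
#'
#' A protein whose hit covers less than `threshold` (default 85%) of the
#' protein is a "long" sequence — the domain sits inside a larger protein;
#' coverage at or above the threshold (strict "lower than" reading) means
#' the protein essentially is the domain ("single_domain").
#'
#' @param hit a `domain_hit` or a numeric protein coverage.
#' @param threshold coverage threshold (default 0.85).
#' @return `"single_domain"` or `"long"`.
#' @export
classify_coverage <- function(hit, threshold = 0.85) {
  cov <- if (is.numeric(hit)) hit else hit$protein_coverage
  if (cov < threshold) "long" else "single_domain"
}

#' Collect seed sequences by pairwise homology to references
#'
#' Database sequences whose best Smith-Waterman hit against any reference
#' satisfies `expect < expect_cutoff` and covers more than `coverage_cutoff`
#' of that reference are returned (the seed-collection rule: E < 1e-5 and
#' reference coverage > 95%). The cheap coverage screen runs before shuffle
#' significance; a sequence that cannot pass coverage is never shuffled, a
#' pure cost optimization with an identical accepted set.
#'
#' @param reference_queries named character vector of reference sequences.
#' @param database named character vector (or `synthetic_proteome`).
#' @param expect_cutoff significance threshold (strict, default 1e-5).
#' @param coverage_cutoff reference-coverage threshold (strict, default
#'   0.95).
#' @param scheme a [scoring_scheme()].
#' @param n_shuffles,seed shuffle-significance parameters.
#' @param trim return only the matched subsequence (the subject interval of
#'   the qualifying alignment, default) rather than the whole database
#'   sequence, so that seeds from multi-domain hosts are domain-sized.
#' @return named character vector of accepted database (sub)sequences
#'   (possibly empty, with a warning).
#' @export
collect_seed <- function(reference_queries, database, expect_cutoff = 1e-5,
                         coverage_cutoff = 0.95, scheme = scoring_scheme(),
                         n_shuffles = 200L, seed = 1L, trim = TRUE) {
  if (inherits(database, "synthetic_proteome")) database <- database$proteins
  if (!length(database)) stop("database is empty", call. = FALSE)
  accepted <- character(0)
  for (i in seq_along(database)) {
    id <- names(database)[i]
    subj <- database[[i]]
    ok <- FALSE
    for (j in seq_along(reference_queries)) {
      ref <- reference_queries[[j]]
      al <- smith_waterman(ref, subj, scheme)
      ref_cov <- (al$query_interval[2] - al$query_interval[1] + 1) / nchar(ref)
      if (!(ref_cov > coverage_cutoff)) next
      sig <- shuffle_significance(ref, subj, scheme, n_shuffles = n_shuffles,
                                  seed = derive_seed(seed, i * 131L + j))
      if (sig$expect < expect_cutoff) {
        ok <- TRUE
        if (trim) subj <- substr(subj, al$subject_interval[1],
                                 al$subject_interval[2])
        break
      }
    }
    if (ok) accepted[id] <- subj
  }
  if (!length(accepted))
    warning("no database sequence passed the seed-collection thresholds")
  accepted
}

#' Write and read the plain-text profile HMM format
#'
#' Versioned named-section text format (HEADER, BACKGROUND, ANCHORS, NODE k)
#' with 12 significant digits; the round trip is lossless at that precision.
#'
#' @param model a `profile_hmm`.
#' @param path file path.
#' @export
write_phmm <- function(model, path) {
  fmt <- function(x) paste(signif(x, 12), collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("HRSURVEY_PHMM 1",
               paste("HEADER", model$profile_id, model$node_count),
               paste("ALPHABET", paste(AA20, collapse = "")),
               paste("BACKGROUND", fmt(model$background))), con)
  if (!is.null(model$anchor_nodes))
    for (i in seq_len(nrow(model$anchor_nodes)))
      writeLines(paste("ANCHOR", model$anchor_nodes$node[i],
                       model$anchor_nodes$residue[i],
                       fmt(model$anchor_nodes$weight[i])), con)
  for (k in seq_len(model$node_count)) {
    writeLines(paste("NODE", k), con)
    writeLines(paste("  MATCH", fmt(model$match_emissions[k, ])), con)
    writeLines(paste("  INSERT", fmt(model$insert_emissions[k, ])), con)
    writeLines(paste("  TRANS", fmt(model$transitions[k, ])), con)
  }
  writeLines(paste("  INSERT0", fmt(model$insert_emissions[model$node_count + 1L, ])), con)
  invisible(path)
}

#' @rdname write_phmm
#' @export
read_phmm <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[[1]], "HRSURVEY_PHMM"))
    stop("not a hrsurvey profile HMM file", call. = FALSE)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  tag <- vapply(toks, `[[`, "", 1L)
  hdr <- toks[[which(tag == "HEADER")[1]]]
  M <- as.integer(hdr[3])
  nums <- function(t) as.numeric(t[-1])
  bg <- nums(toks[[which(tag == "BACKGROUND")[1]]])
  em <- matrix(NA_real_, M, 20L, dimnames = list(NULL, AA20))
  ins <- matrix(NA_real_, M + 1L, 20L, dimnames = list(NULL, AA20))
  trn <- matrix(NA_real_, M, 7L,
                dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  node <- 0L
  anchors <- list()
  for (i in seq_along(toks)) {
    t <- toks[[i]]
    switch(t[1],
           NODE = { node <- as.integer(t[2]) },
           MATCH = { em[node, ] <- nums(t) },
           INSERT = { ins[node, ] <- nums(t) },
           INSERT0 = { ins[M + 1L, ] <- nums(t) },
           TRANS = { trn[node, ] <- nums(t) },
           ANCHOR = { anchors[[length(anchors) + 1L]] <-
             data.frame(node = as.integer(t[2]), residue = t[3],
                        weight = as.numeric(t[4]), stringsAsFactors = FALSE) },
           NULL)
  }
  structure(list(profile_id = hdr[2], node_count = M, match_emissions = em,
                 insert_emissions = ins, transitions = trn,
                 background = setNames(bg, AA20),
                 anchor_nodes = if (length(anchors)) do.call(rbind, anchors) else NULL,
                 match_columns = NULL),
            class = "profile_hmm")
}

#' Write a domain-hit table
#'
#' File coordinates are 1-based inclusive, matching the in-memory hit table.
#'
#' @param hits a hit data.frame from [scan_proteome()].
#' @param path output path.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
read_hits_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
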