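# Independent oracles used by the unit and acceptance tests. All are
# deliberately naive (enumeration, closed form, second implementations) and
# share no code with the package's DP/greedy implementations they check.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_aa <- function(n, seed = NULL) {
  draw <- function() paste(sample(AA20, n, replace = TRUE), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# --- exhaustive local alignment score -----------------------------------
# max over all substring pairs of the exhaustive global affine score;
# exponential recursion, usable only for very short strings.
brute_global_affine <- function(q, s, sub, go, ge) {
  qi <- strsplit(q, "")[[1]]; si <- strsplit(s, "")[[1]]
  nq <- length(qi); ns <- length(si)
  rec <- function(i, j, prev) {
    if (i > nq && j > ns) return(0)
    best <- -Inf
    if (i <= nq && j <= ns)
      best <- max(best, sub[qi[i], si[j]] + rec(i + 1L, j + 1L, "M"))
    if (j <= ns)
      best <- max(best, -(if (prev == "E") ge else go + ge) + rec(i, j + 1L, "E"))
    if (i <= nq)
      best <- max(best, -(if (prev == "F") ge else go + ge) + rec(i + 1L, j, "F"))
    best
  }
  rec(1L, 1L, "S")
}

brute_local_score <- function(q, s, scheme) {
  sub <- scheme$matrix; go <- -scheme$gap_open; ge <- -scheme$gap_extend
  nq <- nchar(q); ns <- nchar(s)
  best <- 0
  for (i1 in seq_len(nq)) for (i2 in i1:nq)
    for (j1 in seq_len(ns)) for (j2 in j1:ns)
      best <- max(best, brute_global_affine(substr(q, i1, i2),
                                            substr(s, j1, j2), sub, go, ge))
  best
}

# --- profile-HMM path enumeration ---------------------------------------
# exhaustive recursion over all local state paths; `tr` rows are the
# transitions out of node k, matching the model layout.
enum_paths <- function(lm, li, tr, x, agg = max) {
  M <- nrow(lm); L <- length(x)
  entry <- -log2(M); exitc <- -log2(M)
  scores <- numeric(0)
  rec <- function(j, k, state, sc) {
    if (state == "M") scores[[length(scores) + 1L]] <<- sc + exitc
    if (k >= M) return(invisible())
    if (state == "M") {
      if (j < L) rec(j + 1L, k + 1L, "M", sc + tr[k, "MM"] + lm[k + 1L, x[j + 1L]])
      if (j < L) rec(j + 1L, k, "I", sc + tr[k, "MI"] + li[k, x[j + 1L]])
      rec(j, k + 1L, "D", sc + tr[k, "MD"])
    } else if (state == "I") {
      if (j < L) rec(j + 1L, k + 1L, "M", sc + tr[k, "IM"] + lm[k + 1L, x[j + 1L]])
      if (j < L) rec(j + 1L, k, "I", sc + tr[k, "II"] + li[k, x[j + 1L]])
    } else {
      if (j < L) rec(j + 1L, k + 1L, "M", sc + tr[k, "DM"] + lm[k + 1L, x[j + 1L]])
      rec(j, k + 1L, "D", sc + tr[k, "DD"])
    }
  }
  for (j in seq_len(L)) for (k in seq_len(M))
    rec(j, k, "M", entry + lm[k, x[j]])
  if (!length(scores)) return(NA_real_)
  agg(unlist(scores))
}

logsumexp2 <- function(v) { m <- max(v); m + log2(sum(2^(v - m))) }

# random tiny profile HMM in the package's log-odds layout
random_tiny_model <- function(M, seed) {
  withr::with_seed(seed, {
    bg <- rep(1 / 20, 20)
    em <- matrix(rgamma(M * 20, 1), M, 20); em <- em / rowSums(em)
    ins <- matrix(rgamma(M * 20, 1), M, 20); ins <- ins / rowSums(ins)
    tr <- matrix(rgamma(M * 7, 1), M, 7,
                 dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
    tr[, 1:3] <- tr[, 1:3, drop = FALSE] / rowSums(tr[, 1:3, drop = FALSE])
    tr[, 4:5] <- tr[, 4:5, drop = FALSE] / rowSums(tr[, 4:5, drop = FALSE])
    tr[, 6:7] <- tr[, 6:7, drop = FALSE] / rowSums(tr[, 6:7, drop = FALSE])
    list(lm = log2(em) - rep(log2(bg), each = M),
         li = log2(ins) - rep(log2(bg), each = M),
         tr = log2(tr))
  })
}

# --- 3-taxon likelihood by root-state enumeration -----------------------
enum_star_loglik <- function(tip_seqs, branch_lengths, model) {
  mats <- lapply(model$category_rates, function(r)
    lapply(branch_lengths, function(t) transition_matrix(model, t, r)))
  codes <- lapply(tip_seqs, function(s) match(strsplit(s, "")[[1]], AA20))
  L <- length(codes[[1]])
  ll <- 0
  for (site in seq_len(L)) {
    site_lik <- 0
    for (g in seq_along(model$category_rates)) {
      lik_g <- 0
      for (r in 1:20) {
        p <- model$frequencies[r]
        for (tip in seq_along(codes))
          p <- p * mats[[g]][[tip]][r, codes[[tip]][site]]
        lik_g <- lik_g + p
      }
      site_lik <- site_lik + model$category_weights[g] * lik_g
    }
    ll <- ll + log(site_lik)
  }
  ll
}

# --- second implementation of the overlap-resolution rule ---------------
resolve_overlaps_oracle <- function(hits) {
  remaining <- hits
  accepted <- hits[0, , drop = FALSE]
  while (nrow(remaining)) {
    len <- remaining$env_end - remaining$env_start
    pick <- which(remaining$evalue == min(remaining$evalue))
    if (length(pick) > 1L) pick <- pick[len[pick] == max(len[pick])]
    if (length(pick) > 1L)
      pick <- pick[order(remaining$profile_id[pick])][1L]
    cand <- remaining[pick[1L], , drop = FALSE]
    remaining <- remaining[-pick[1L], , drop = FALSE]
    clash <- FALSE
    if (nrow(accepted))
      clash <- any(pmin(accepted$env_end, cand$env_end) -
                     pmax(accepted$env_start, cand$env_start) >= 0L)
    if (!clash) accepted <- rbind(accepted, cand)
  }
  accepted[order(accepted$env_start), , drop = FALSE]
}

random_hit_set <- function(n, seed) {
  withr::with_seed(seed, {
    start <- sample.int(200L, n, replace = TRUE)
    data.frame(protein_id = "p1",
               profile_id = sample(c("A", "B", "C", "D"), n, replace = TRUE),
               evalue = signif(10^runif(n, -12, -1), 2),
               env_start = start,
               env_end = start + sample.int(80L, n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

# --- brute-force k-mer distance -----------------------------------------
brute_kmer_dist <- function(a, b, k = 3L) {
  km <- function(s) {
    if (nchar(s) < k) return(character(0))
    unique(vapply(seq_len(nchar(s) - k + 1L),
                  function(i) substr(s, i, i + k - 1L), ""))
  }
  ka <- km(a); kb <- km(b)
  if (!length(ka) || !length(kb)) return(1)
  1 - length(intersect(ka, kb)) / min(length(ka), length(kb))
}

# --- quadrature oracle for discrete-gamma category means ----------------
quadrature_gamma_rates <- function(alpha, k) {
  q <- qgamma((0:k) / k, shape = alpha, rate = alpha)
  vapply(seq_len(k), function(i) {
    up <- if (is.finite(q[i + 1])) q[i + 1] else qgamma(1 - 1e-12, alpha, alpha)
    k * integrate(function(x) x * dgamma(x, shape = alpha, rate = alpha),
                  q[i], up, rel.tol = 1e-10)$value
  }, 1)
}
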