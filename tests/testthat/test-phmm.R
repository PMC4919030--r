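test_that("match-column selection follows the occupancy rule", {
  # gap-free alignment: every column is a node
  aln <- c(a = "ACDEF", b = "ACDEF", c = "ACDFF")
  expect_identical(build_phmm(aln)$node_count, 5L)
  # a column at 1/3 occupancy (< 0.5) becomes an insert state
  gappy <- c(a = "AC", b = "A-", c = "A-")
  expect_identical(build_phmm(gappy)$node_count, 1L)
  expect_identical(build_phmm(gappy, match_rule = 1 / 4)$node_count, 2L)
  expect_error(build_phmm(c(a = "--", b = "--", c = "AC"), match_rule = 0.9),
               "empty model")
  expect_error(build_phmm(c(a = "AC")), ">= 2 rows")
})

test_that("anchor weighting multiplies the stated residue count before smoothing", {
  # column with counts {H:3, N:1}, anchor weight 5, pseudocount 1:
  # e(H) = (3*5 + 1) / ((15+1) + (1+1) + 18*1) = 16/36
  aln <- c(a = "HA", b = "HA", c = "HA", d = "NA")
  hmm <- build_phmm(aln, anchors = data.frame(column = 1, residue = "H",
                                              weight = 5))
  expect_equal(unname(hmm$match_emissions[1, "H"]), 16 / 36)
  expect_equal(unname(hmm$match_emissions[1, "N"]), 2 / 36)
  expect_equal(unname(hmm$match_emissions[1, "C"]), 1 / 36)
})

test_that("emissions and transition groups are normalized after every build", {
  for (seed in 1:5) {
    rows <- vapply(1:6, function(i) random_aa(30, seed = seed * 100 + i), "")
    names(rows) <- paste0("r", 1:6)
    aln <- progressive_align(rows)
    hmm <- build_phmm(aln)
    expect_lt(max(abs(rowSums(hmm$match_emissions) - 1)), 1e-9)
    expect_lt(max(abs(rowSums(hmm$insert_emissions) - 1)), 1e-9)
    tr <- hmm$transitions
    expect_lt(max(abs(rowSums(tr[, c("MM", "MI", "MD")]) - 1)), 1e-9)
    expect_lt(max(abs(rowSums(tr[, c("IM", "II")]) - 1)), 1e-9)
    expect_lt(max(abs(rowSums(tr[, c("DM", "DD")]) - 1)), 1e-9)
  }
})

test_that("Viterbi DP equals exhaustive path enumeration on tiny models", {
  for (i in 1:100) {
    M <- sample(1:3, 1); L <- sample(1:4, 1)
    parts <- random_tiny_model(M, seed = 1000 + i)
    x <- withr::with_seed(2000 + i, sample.int(20, L, replace = TRUE))
    got <- hrsurvey:::.phmm_viterbi(parts$lm, parts$li, parts$tr, x - 1L)$score
    want <- enum_paths(parts$lm, parts$li, parts$tr, x, agg = max)
    expect_equal(got, want, tolerance = 1e-10, info = paste("case", i))
  }
})

test_that("Forward equals path-sum enumeration and dominates Viterbi", {
  for (i in 1:30) {
    M <- sample(1:3, 1); L <- sample(1:4, 1)
    parts <- random_tiny_model(M, seed = 3000 + i)
    x <- withr::with_seed(4000 + i, sample.int(20, L, replace = TRUE))
    fwd <- hrsurvey:::.phmm_forward(parts$lm, parts$li, parts$tr, x - 1L)
    vit <- hrsurvey:::.phmm_viterbi(parts$lm, parts$li, parts$tr, x - 1L)$score
    expect_equal(fwd, enum_paths(parts$lm, parts$li, parts$tr, x,
                                 agg = logsumexp2), tolerance = 1e-8)
    expect_gte(fwd, vit - 1e-10)
  }
  # on realistic models too
  tpl <- make_default_templates(1)$hemerythrin
  rows <- setNames(vapply(1:8, function(i)
    mutate_from_template(tpl, 0.3, seed = i), ""), paste0("r", 1:8))
  hmm <- build_phmm(progressive_align(rows))
  for (i in 1:5) {
    s <- mutate_from_template(tpl, 0.5, seed = 50 + i)
    expect_gte(forward_score(hmm, s), viterbi_scan(hmm, s)$bit_score)
  }
})

test_that("scanning the consensus of a sharp model covers every node", {
  tpl <- make_default_templates(1)$hemerythrin
  rows <- setNames(rep(tpl$consensus, 4), paste0("r", 1:4))
  hmm <- build_phmm(rows, pseudocount = 0.01)
  hit <- viterbi_scan(hmm, tpl$consensus)
  expect_identical(hit$profile_span, c(1L, 118L))
  expect_equal(hit$reference_coverage, 1.0)
  expect_equal(hit$protein_coverage, 1.0)
  expect_gt(hit$bit_score, 100)
})

test_that("forward score grows when consensus residues are appended", {
  tpl <- make_default_templates(2)$hemerythrin
  rows <- setNames(vapply(1:6, function(i)
    mutate_from_template(tpl, 0.2, seed = i), ""), paste0("r", 1:6))
  hmm <- build_phmm(progressive_align(rows))
  prefix <- substr(tpl$consensus, 1, 60)
  scores <- vapply(c(70, 90, 110), function(n)
    forward_score(hmm, substr(tpl$consensus, 1, n)), 1)
  expect_true(all(diff(scores) > 0))
  expect_gt(scores[3], forward_score(hmm, prefix))
})

test_that("anchor weighting widens the gap between anchor-keepers and violators", {
  tpl <- make_default_templates(1)$hemerythrin
  loose <- domain_template("loose", tpl$consensus, tpl$anchor_positions,
                           tpl$anchor_residues, anchor_conservation = 0)
  rows <- setNames(vapply(1:10, function(i)
    mutate_from_template(tpl, 0.25, seed = 70 + i), ""), paste0("r", 1:10))
  aln <- progressive_align(rows)
  anchors <- data.frame(column = tpl$anchor_positions,
                        residue = tpl$anchor_residues, weight = 5)
  hmm_flat <- build_phmm(aln, profile_id = "hr")
  hmm_anch <- build_phmm(aln, anchors = anchors, profile_id = "hr")
  wider <- 0
  n_pairs <- 30
  for (i in seq_len(n_pairs)) {
    keeper <- mutate_from_template(tpl, 0.35, seed = 100 + i)
    violator <- mutate_from_template(loose, 0.35, seed = 100 + i)
    gap_flat <- viterbi_scan(hmm_flat, keeper)$bit_score -
      viterbi_scan(hmm_flat, violator)$bit_score
    gap_anch <- viterbi_scan(hmm_anch, keeper)$bit_score -
      viterbi_scan(hmm_anch, violator)$bit_score
    wider <- wider + (gap_anch > gap_flat)
  }
  expect_gte(wider / n_pairs, 0.9)
})

test_that("sister-family sequences score below the planted family", {
  tpl <- make_default_templates(1)
  rows <- setNames(vapply(1:10, function(i)
    mutate_from_template(tpl$hemerythrin, 0.3, seed = 200 + i), ""),
    paste0("r", 1:10))
  aln <- progressive_align(rows)
  hmm <- build_phmm(aln, anchors = anchor_columns(aln, tpl$hemerythrin))
  worse <- 0
  for (i in 1:20) {
    hr <- viterbi_scan(hmm, mutate_from_template(tpl$hemerythrin, 0.5,
                                                 seed = 300 + i))$bit_score
    sis <- viterbi_scan(hmm, mutate_from_template(tpl$sister_hhe, 0.5,
                                                  seed = 300 + i))$bit_score
    worse <- worse + (sis < hr)
  }
  expect_gte(worse / 20, 0.95)
})

test_that("E-value calibration has Gumbel tail limits and is reproducible", {
  tpl <- make_default_templates(1)$hemerythrin
  rows <- setNames(vapply(1:6, function(i)
    mutate_from_template(tpl, 0.2, seed = 400 + i), ""), paste0("r", 1:6))
  hmm <- build_phmm(progressive_align(rows))
  cal <- calibrate_evalue(hmm, n_random = 200, length = 200, seed = 5)
  cal2 <- calibrate_evalue(hmm, n_random = 200, length = 200, seed = 5)
  expect_identical(cal$gumbel_mu, cal2$gumbel_mu)
  expect_gt(cal$gumbel_lambda, 0)
  expect_equal(evalue(cal, 1e6, 10000), 0)
  expect_equal(evalue(cal, -1e6, 10000), 10000)
  expect_true(evalue(cal, 10, 10000) >= evalue(cal, 50, 10000))
  expect_error(calibrate_evalue(hmm, n_random = 50), ">= 100")
})

test_that("planted domains separate cleanly from decoys under the E-value", {
  b <- planted_domain_benchmark(n_planted = 40, n_decoys = 300, seed = 7)
  expect_gte(b$sensitivity, 0.95)
  expect_lte(b$fdr, 0.01)
  expect_true(all(b$hits$evalue < 1e-5))
})

test_that("coverage classification uses the strict 85% boundary", {
  expect_identical(classify_coverage(0.84), "long")
  expect_identical(classify_coverage(0.85), "single_domain")
  expect_identical(classify_coverage(1.0), "single_domain")
})

test_that("seed collection applies both the expect and coverage rules", {
  tpl <- make_default_templates(5)
  refs <- c(ref = tpl$hemerythrin$consensus)
  # the references themselves are always recovered
  self <- collect_seed(refs, c(db1 = tpl$hemerythrin$consensus), seed = 1)
  expect_identical(length(self), 1L)
  # impossible coverage threshold: empty result with a warning
  expect_warning(
    none <- collect_seed(refs, c(db1 = tpl$hemerythrin$consensus),
                         coverage_cutoff = 1.01, seed = 1),
    "no database sequence")
  expect_identical(length(none), 0L)
  # planted vs decoy fixture
  planted <- setNames(vapply(1:25, function(i)
    mutate_from_template(tpl$hemerythrin, 0.35, seed = 500 + i), ""),
    sprintf("planted%02d", 1:25))
  decoys <- setNames(vapply(1:100, function(i) random_aa(150, seed = 600 + i), ""),
                     sprintf("decoy%03d", 1:100))
  got <- collect_seed(refs, c(planted, decoys), seed = 2)
  expect_gte(sum(startsWith(names(got), "planted")), 23L)
  expect_identical(sum(startsWith(names(got), "decoy")), 0L)
})

test_that("profile HMM text format round-trips losslessly", {
  tpl <- make_default_templates(1)$hemerythrin
  rows <- setNames(vapply(1:5, function(i)
    mutate_from_template(tpl, 0.3, seed = 700 + i), ""), paste0("r", 1:5))
  aln <- progressive_align(rows)
  hmm <- build_phmm(aln, anchors = anchor_columns(aln, tpl), profile_id = "hr")
  path <- tempfile(fileext = ".phmm")
  write_phmm(hmm, path)
  back <- read_phmm(path)
  expect_identical(back$profile_id, hmm$profile_id)
  expect_identical(back$node_count, hmm$node_count)
  expect_equal(back$match_emissions, hmm$match_emissions, tolerance = 1e-11)
  expect_equal(back$transitions, hmm$transitions, tolerance = 1e-11)
  expect_equal(back$background, hmm$background, tolerance = 1e-11)
  expect_equal(back$anchor_nodes$node, hmm$anchor_nodes$node)
  # and the round-tripped model scores identically (to format precision)
  probe <- mutate_from_template(tpl, 0.4, seed = 99)
  expect_equal(viterbi_scan(back, probe)$bit_score,
               viterbi_scan(hmm, probe)$bit_score, tolerance = 1e-8)
})
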