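#' Planted-domain recovery benchmark
#'
#' The package's standing sensitivity/specificity check for the profile-HMM
#' search. A hemerythrin-analogue profile is trained on its own simulated
#' homolog sample (aligned, anchor-weighted), then scanned against a mixed
#' database of planted single-domain homologs and decoys (background
#' sequences and unrelated decoy-domain proteins). A planted protein counts
#' as recovered when a hit with `evalue < detect_expect` overlaps its true
#' domain interval; any reported decoy hit is a false discovery.
#'
#' @param n_planted planted hemerythrin-analogue proteins (default 200).
#' @param n_decoys decoy proteins (default 2000).
#' @param divergence_range planted divergence range (default 0.1-0.5
#'   substitutions/site).
#' @param detect_expect detection threshold (default 1e-5).
#' @param database_size E-value scaling (default 10000).
#' @param seed integer seed (default 42, the benchmark's defining seed).
#' @return list with `sensitivity`, `fdr`, `n_planted`, `n_decoys`,
#'   `n_detected`, `hits`.
#' @export
planted_domain_benchmark <- function(n_planted = 200L, n_decoys = 2000L,
                                     divergence_range = c(0.1, 0.5),
                                     detect_expect = 1e-5,
                                     database_size = 10000L, seed = 42L) {
  tpl <- make_default_templates(seed = derive_seed(seed, 1L))
  hr <- tpl$hemerythrin
  model <- lg_model()
  scheme <- scoring_scheme()
  # training homologs -> seed alignment -> anchored profile
  train <- withr::with_seed(derive_seed(seed, 2L), {
    setNames(vapply(seq_len(30L), function(i)
      mutate_from_template(hr, runif(1, divergence_range[1], divergence_range[2]),
                           seed = sample.int(2^31 - 2, 1L)), ""),
      sprintf("train%02d", seq_len(30L)))
  })
  seed_aln <- progressive_align(train, scheme)
  hmm <- build_phmm(seed_aln, anchors = anchor_columns(seed_aln, hr),
                    profile_id = "hemerythrin")
  # database: planted singles with short flanks, plus decoys
  db <- withr::with_seed(derive_seed(seed, 3L), {
    freqs <- model$frequencies
    flank <- function(n) if (n) paste(sample(AA20, n, TRUE, freqs), collapse = "") else ""
    planted <- vapply(seq_len(n_planted), function(i) {
      d <- runif(1, divergence_range[1], divergence_range[2])
      paste0(flank(sample(0:10, 1)),
             mutate_from_template(hr, d, seed = sample.int(2^31 - 2, 1L)),
             flank(sample(0:10, 1)))
    }, "")
    decoys <- vapply(seq_len(n_decoys), function(i) {
      u <- runif(1)
      if (u < 0.1)
        mutate_from_template(tpl$decoys[[1]], runif(1, 0.1, 0.5),
                             seed = sample.int(2^31 - 2, 1L))
      else if (u < 0.2)
        mutate_from_template(tpl$decoys[[2]], runif(1, 0.1, 0.5),
                             seed = sample.int(2^31 - 2, 1L))
      else paste(sample(AA20, sample(80:400, 1), TRUE, freqs), collapse = "")
    }, "")
    setNames(c(planted, decoys),
             c(sprintf("planted%04d", seq_len(n_planted)),
               sprintf("decoy%04d", seq_len(n_decoys))))
  })
  calib <- calibrate_evalue(hmm, n_random = 1000L, length = 300L,
                            seed = derive_seed(seed, 4L))
  hits <- scan_proteome(hmm, db, calibration = calib,
                        evalue_cutoff = detect_expect,
                        database_size = database_size)
  planted_ids <- sprintf("planted%04d", seq_len(n_planted))
  detected_planted <- intersect(unique(hits$protein_id), planted_ids)
  false_hits <- setdiff(unique(hits$protein_id), planted_ids)
  n_detected <- length(unique(hits$protein_id))
  list(sensitivity = length(detected_planted) / n_planted,
       fdr = if (n_detected) length(false_hits) / n_detected else 0,
       n_planted = n_planted, n_decoys = n_decoys,
       n_detected = n_detected, hits = hits)
}

#' Two-family monophyly recovery benchmark
#'
#' Simulates the separation of the oxygen-binding family from its sister
#' family: sequences evolve under LG+Gamma on a two-clade tree (one clade
#' per family) joined by a long internal branch, the ML tree is re-inferred
#' with NNI search, aLRT supports are computed and branches below 0.6
#' collapsed, the tree is midpoint rooted, and the focal family is tested
#' for monophyly.
#'
#' @param n_per_clade tips per family (default 5).
#' @param n_sites alignment columns (default 200).
#' @param alpha gamma shape used for both simulation and inference
#'   (default 1.151).
#' @param inner_branch length of the stem separating the families
#'   (default 0.5).
#' @param collapse_threshold aLRT collapse threshold (default 0.6).
#' @param seed integer seed.
#' @return list with `monophyletic` (logical), `tree`, `true_tree`.
#' @export
monophyly_benchmark <- function(n_per_clade = 5L, n_sites = 200L,
                                alpha = 1.151, inner_branch = 0.5,
                                collapse_threshold = 0.6, seed = 1L) {
  clade <- function(labs, seed) {
    tr <- withr::with_seed(seed, ape::rcoal(length(labs), tip.label = labs))
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * 0.4
    tr
  }
  hr_tips <- sprintf("hr%02d", seq_len(n_per_clade))
  sis_tips <- sprintf("sis%02d", seq_len(n_per_clade))
  t1 <- clade(hr_tips, derive_seed(seed, 1L))
  t2 <- clade(sis_tips, derive_seed(seed, 2L))
  txt <- sprintf("(%s:%f,%s:%f);",
                 sub(";$", "", ape::write.tree(t1)), inner_branch / 2,
                 sub(";$", "", ape::write.tree(t2)), inner_branch / 2)
  true_tree <- ape::read.tree(text = txt)
  model <- lg_model(gamma_shape = alpha, n_categories = 6L)
  aln <- evolve_along_tree(true_tree, n_sites, model,
                           seed = derive_seed(seed, 3L))
  ml <- ml_tree(aln, gamma_shape = alpha, n_categories = 6L)
  tree <- alrt_support(ml)
  tree <- collapse_low_support(tree, collapse_threshold)
  tree <- midpoint_root(tree)
  list(monophyletic = is_monophyletic_clade(tree, hr_tips),
       tree = tree, true_tree = true_tree)
}

#' Topology and gamma-shape recovery benchmark
#'
#' Simulates alignments on a fixed 8-taxon tree under LG+Gamma with
#' alpha = 1.151 and re-infers the tree with the gamma shape co-estimated;
#' reports whether the true topology is recovered exactly (Robinson-Foulds
#' distance 0) and the estimated alpha.
#'
#' @param n_sites alignment columns (default 500).
#' @param alpha simulation gamma shape (default 1.151).
#' @param seed integer seed.
#' @return list with `rf` (integer), `alpha_hat`, `true_tree`, `tree`.
#' @export
recovery_benchmark <- function(n_sites = 500L, alpha = 1.151, seed = 1L) {
  true_tree <- ape::read.tree(text = paste0(
    "(((t1:0.15,t2:0.2):0.12,(t3:0.18,t4:0.25):0.1):0.08,",
    "((t5:0.22,t6:0.15):0.15,t7:0.3):0.05,t8:0.35);"))
  model <- lg_model(gamma_shape = alpha, n_categories = 6L)
  aln <- evolve_along_tree(true_tree, n_sites, model,
                           seed = derive_seed(seed, 7L))
  ml <- ml_tree(aln, gamma_shape = "auto", n_categories = 6L)
  list(rf = rf_distance(true_tree, ml$tree), alpha_hat = ml$alpha,
       true_tree = true_tree, tree = ml$tree)
}

#' Gumbel moment-fit recovery
#'
#' Draws a large sample from a known Gumbel distribution and refits it by
#' the method of moments, reporting relative parameter errors.
#'
#' @param n sample size (default 10000).
#' @param mu,lambda true parameters (defaults 20 and 0.3).
#' @param seed integer seed.
#' @return list with `mu_hat`, `lambda_hat`, `mu_rel_err`,
#'   `lambda_rel_err`.
#' @export
gumbel_recovery <- function(n = 10000L, mu = 20, lambda = 0.3, seed = 1L) {
  x <- withr::with_seed(seed, mu - log(-log(runif(n))) / lambda)
  fit <- fit_gumbel(x)
  list(mu_hat = fit$mu, lambda_hat = fit$lambda,
       mu_rel_err = abs(fit$mu - mu) / mu,
       lambda_rel_err = abs(fit$lambda - lambda) / lambda)
}
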