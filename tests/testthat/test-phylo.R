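test_that("discrete gamma categories match a quadrature oracle", {
  expect_identical(discretize_gamma(1.5, 1)$rates, 1)
  g_big <- discretize_gamma(1e4, 6)
  expect_true(all(abs(g_big$rates - 1) < 0.05))  # alpha -> infinity limit
  # spread shrinks monotonically as alpha grows
  expect_lt(diff(range(discretize_gamma(100, 6)$rates)),
            diff(range(discretize_gamma(10, 6)$rates)))
  g <- discretize_gamma(1.151, 6)
  expect_equal(g$rates, quadrature_gamma_rates(1.151, 6), tolerance = 1e-6)
  expect_equal(sum(g$rates * g$weights), 1, tolerance = 1e-12)
  expect_error(discretize_gamma(-1, 6), "alpha")
  expect_error(discretize_gamma(2, 0), "n_categories")
})

test_that("transition matrices are stochastic and start at identity", {
  m <- lg_model(1.151, 6)
  for (t in c(0, 0.1, 1, 10)) {
    P <- transition_matrix(m, t)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_true(all(P >= 0))
  }
  expect_equal(unname(transition_matrix(m, 0)), diag(20), tolerance = 1e-12)
  # detailed balance: pi_i P_ij = pi_j P_ji (reversibility)
  P <- transition_matrix(m, 0.5)
  F <- m$frequencies * P
  expect_lt(max(abs(F - t(F))), 1e-12)
  expect_error(transition_matrix(m, -1), "negative")
})

test_that("NJ is exact on additive distances and clamps negatives", {
  true <- ape::read.tree(text = "((a:0.1,b:0.3):0.2,(c:0.25,d:0.15):0.1);")
  dm <- ape::cophenetic.phylo(true)
  got <- nj_tree(dm)
  expect_equal(rf_distance(got, true), 0)
  expect_equal(ape::cophenetic.phylo(got)[rownames(dm), colnames(dm)], dm,
               tolerance = 1e-10)
  # n < 3: trivial two-tip tree
  d2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_identical(sort(nj_tree(d2)$tip.label), c("a", "b"))
})

test_that("pruning likelihood equals root-state enumeration on 3-taxon stars", {
  model <- lg_model(gamma_shape = 0.8, n_categories = 4)
  tr <- ape::read.tree(text = "(a:0.2,b:0.45,c:0.7);")
  for (i in 1:3) {
    n_sites <- c(2, 10, 25)[i]
    aln <- evolve_along_tree(tr, n_sites, model, seed = 40 + i)
    want <- enum_star_loglik(list(aln[["a"]], aln[["b"]], aln[["c"]]),
                             c(0.2, 0.45, 0.7), model)
    got <- tree_log_likelihood(tr, aln, model)
    expect_lt(abs(got - want) / abs(want), 1e-10)
  }
})

test_that("degenerate and saturated trees reduce to equilibrium products", {
  model <- lg_model(gamma_shape = 1, n_categories = 1)
  # one tip: sum of log frequencies
  aln1 <- c(a = "ARND")
  expect_equal(tree_log_likelihood(NULL, aln1, model),
               sum(log(model$frequencies[c("A", "R", "N", "D")])))
  # saturation: long branches make tips independent draws from equilibrium
  tr <- ape::read.tree(text = "(a:50,b:50,c:50);")
  aln <- evolve_along_tree(tr, 5, model, seed = 9)
  want <- sum(vapply(1:5, function(s) {
    sum(log(model$frequencies[vapply(aln, function(r)
      substr(r, s, s), "")]))
  }, 1))
  expect_equal(tree_log_likelihood(tr, aln, model), want, tolerance = 1e-6)
})

test_that("likelihood is invariant to sliding length across the root (pulley)", {
  model <- lg_model(gamma_shape = 1.2, n_categories = 3)
  t1 <- ape::read.tree(text = "((a:0.2,b:0.3):0.25,(c:0.15,d:0.4):0.05);")
  t2 <- ape::read.tree(text = "((a:0.2,b:0.3):0.1,(c:0.15,d:0.4):0.2);")
  aln <- evolve_along_tree(t1, 60, model, seed = 3)
  expect_equal(tree_log_likelihood(t1, aln, model),
               tree_log_likelihood(t2, aln, model), tolerance = 1e-8)
})

test_that("optimizing the true topology never scores below the NJ start", {
  true_tree <- ape::read.tree(text = paste0(
    "(((t1:0.15,t2:0.2):0.12,(t3:0.18,t4:0.25):0.1):0.08,",
    "((t5:0.22,t6:0.15):0.15,t7:0.3):0.05,t8:0.35);"))
  model <- lg_model(1.151, 6)
  for (s in 1:10) {
    aln <- evolve_along_tree(true_tree, 300, model, seed = 2600 + s)
    ml_true <- ml_tree(aln, gamma_shape = 1.151,
                       optimize_topology = FALSE, start = true_tree)
    ml_nj <- ml_tree(aln, gamma_shape = 1.151, optimize_topology = FALSE)
    expect_gte(ml_true$log_likelihood, ml_nj$log_likelihood - 1e-6)
    # the optimizer is monotone: it never returns less than its start point
    start_ll <- tree_log_likelihood(true_tree, aln, model)
    expect_gte(ml_true$log_likelihood, start_ll - 1e-6)
  }
})

test_that("aLRT supports behave at the boundaries and under relabelling", {
  model <- lg_model(1.151, 6)
  tr <- ape::read.tree(text = "((a:0.3,b:0.3):0.4,(c:0.3,d:0.3):0.1,e:0.4);")
  aln <- evolve_along_tree(tr, 400, model, seed = 12)
  ml <- ml_tree(aln, gamma_shape = 1.151)
  sup <- alrt_support(ml)
  vals <- suppressWarnings(as.numeric(sup$node.label))
  vals <- vals[!is.na(vals)]
  expect_true(all(vals >= 0 & vals <= 1))
  # the long internal branch gets strong support
  expect_gte(max(vals), 0.9)
  # zero-length internal branches: all NNI configurations have equal
  # likelihood (topological indistinguishability), hence zero statistic
  tr0 <- ape::read.tree(text = "((a:0.3,b:0.3):0,(c:0.3,d:0.3):0,e:0.4);")
  aln0 <- evolve_along_tree(ape::read.tree(
    text = "(a:0.3,b:0.3,c:0.3,d:0.3,e:0.4);"), 200, model, seed = 13)
  l0 <- tree_log_likelihood(tr0, aln0, model)
  nbs <- phangorn::nni(tr0)
  for (i in seq_along(nbs))
    expect_equal(tree_log_likelihood(nbs[[i]], aln0, model), l0,
                 tolerance = 1e-6)
})

test_that("collapse contracts exactly the low-support branches, idempotently", {
  tr <- ape::read.tree(text = "(((a:1,b:2)0.95:0.5,(c:1,d:1)0.3:0.4)0.7:0.2,(e:1,f:1)0.5:0.3,g:2);")
  col <- collapse_low_support(tr, 0.6)
  # 0.3 and 0.5 nodes collapse, 0.95 and 0.7 stay
  expect_identical(col$Nnode, tr$Nnode - 2L)
  expect_true(is_monophyletic_clade(col, c("a", "b")))
  expect_false(ape::is.monophyletic(col, c("c", "d")))
  # tip set preserved, surviving branch lengths preserved
  expect_identical(sort(col$tip.label), sort(tr$tip.label))
  expect_identical(unname(ape::cophenetic.phylo(col)["a", "b"]), 3)
  # idempotent
  col2 <- collapse_low_support(col, 0.6)
  expect_identical(ape::write.tree(col2), ape::write.tree(col))
  # all high -> unchanged; all low -> star
  keep <- collapse_low_support(tr, 0.2)
  expect_identical(keep$Nnode, tr$Nnode)
  star <- collapse_low_support(tr, 1.1)
  expect_identical(star$Nnode, 1L)
})

test_that("midpoint rooting bisects the tree diameter", {
  # two tips: root at d/2
  t2 <- midpoint_root(ape::read.tree(text = "(a:0.8,b:0.2);"))
  dd <- ape::dist.nodes(t2)
  root <- length(t2$tip.label) + 1L
  expect_equal(unname(dd[root, 1:2]), c(0.5, 0.5))
  for (i in 1:50) {
    tr <- withr::with_seed(i, ape::rtree(sample(4:12, 1)))
    mp <- midpoint_root(tr)
    coph <- ape::cophenetic.phylo(tr)
    diam <- max(coph)  # all-pairs path-length oracle
    ddm <- ape::dist.nodes(mp)
    rootm <- length(mp$tip.label) + 1L
    expect_equal(max(ddm[rootm, seq_len(length(mp$tip.label))]), diam / 2,
                 tolerance = 1e-8, info = paste("tree", i))
    # re-rooting preserves all pairwise tip distances
    cophm <- ape::cophenetic.phylo(mp)[rownames(coph), colnames(coph)]
    expect_equal(cophm, coph, tolerance = 1e-8)
  }
})

test_that("monophyly testing handles trivial and error cases", {
  tr <- ape::read.tree(text = "(((a:1,b:1):1,c:2):1,(d:1,e:1):2);")
  expect_true(is_monophyletic_clade(tr, c("a", "b")))
  expect_true(is_monophyletic_clade(tr, c("a", "b", "c")))
  expect_false(is_monophyletic_clade(tr, c("a", "c", "d")))
  expect_true(is_monophyletic_clade(tr, "a"))                 # singleton
  expect_true(is_monophyletic_clade(tr, tr$tip.label))        # full set
  expect_error(is_monophyletic_clade(tr, c("a", "zz")), "unknown tip")
})

test_that("bootstrap proportions mark well-supported bipartitions", {
  model <- lg_model(1.151, 6)
  tr <- ape::read.tree(text = "((a:0.2,b:0.2):0.5,(c:0.2,d:0.2):0.5,e:0.4);")
  aln <- evolve_along_tree(tr, 300, model, seed = 21)
  ml <- ml_tree(aln, gamma_shape = 1.151)
  bs <- bootstrap_support(ml, n_replicates = 20, seed = 5,
                          optimize_topology = FALSE)
  v <- suppressWarnings(as.numeric(bs$node.label))
  v <- v[!is.na(v)]
  expect_true(all(v >= 0 & v <= 1))
  expect_gte(max(v), 0.9)  # the deep split is essentially certain
})
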