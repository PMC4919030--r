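#' Alignment to phangorn phyDat
#' @keywords internal
#' @noRd
as_phydat <- function(aln) {
  check_alignment(aln)
  phangorn::phyDat(do.call(rbind, strsplit(aln, "")), type = "AA")
}

#' Neighbor-joining starting tree
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]); negative branch length
#' estimates are clamped to zero. With fewer than 3 taxa a trivial tree is
#' returned.
#'
#' @param dm symmetric distance matrix with labels.
#' @return unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3L) {
    tree <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);",
                                          rownames(dm)[1], dm[1, 2] / 2,
                                          rownames(dm)[2], dm[1, 2] / 2))
    return(tree)
  }
  tree <- ape::nj(as.dist(dm))
  if (any(tree$edge.length < 0)) {
    message(sum(tree$edge.length < 0),
            " negative NJ branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Log likelihood of a tree under LG+Gamma
#'
#' Felsenstein-pruning log likelihood (natural log) of a gap-free or gapped
#' alignment, averaged over the discrete gamma categories; gaps and `X` are
#' treated as missing data. Computation is delegated to
#' [phangorn::pml()] with the LG model; the degenerate one-tip case is the
#' sum of log equilibrium frequencies.
#'
#' @param tree `ape::phylo`; tip labels must match alignment names.
#' @param aln named character vector alignment.
#' @param model a [lg_model()] (gamma shape and category count are taken
#'   from it).
#' @return numeric log likelihood.
#' @export
tree_log_likelihood <- function(tree, aln, model = lg_model()) {
  if (length(aln) == 1L) {
    codes <- aa_encode(ungap(aln[[1]]), extra = "X")
    codes <- codes[codes <= 20L]
    return(sum(log(model$frequencies[codes])))
  }
  if (!setequal(tree$tip.label, names(aln)))
    stop("tree tips and alignment rows disagree", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch length", call. = FALSE)
  fit <- phangorn::pml(tree, as_phydat(aln), model = "LG",
                       k = model$n_categories, shape = model$gamma_shape)
  as.numeric(stats::logLik(fit))
}

#' Maximum-likelihood tree under LG+Gamma
#'
#' NJ starting tree (maximum-likelihood pairwise distances), then iterated
#' branch-length optimization and (optionally) NNI topology search, with the
#' gamma shape either fixed or co-estimated. Fitting is delegated to
#' [phangorn::optim.pml()].
#'
#' @param aln named character vector alignment (>= 3 rows for a meaningful
#'   topology).
#' @param gamma_shape fixed alpha, or `"auto"` to estimate it.
#' @param n_categories discrete gamma categories (default 6).
#' @param optimize_topology run the NNI hill-climb (default TRUE).
#' @param start optional starting `phylo` tree.
#' @return object of class `ml_fit`: list with `tree` (unrooted, optimized
#'   branch lengths), `log_likelihood`, `alpha`, `n_categories`, `fit` (the
#'   underlying `pml` object), `aln`.
#' @export
ml_tree <- function(aln, gamma_shape = "auto", n_categories = 6L,
                    optimize_topology = TRUE, start = NULL) {
  dat <- as_phydat(aln)
  tr <- start
  if (is.null(tr)) {
    dm <- as.matrix(phangorn::dist.ml(dat))
    tr <- nj_tree(dm)
  }
  tr <- ape::unroot(tr)
  tr$edge.length[tr$edge.length < 1e-8] <- 1e-8
  auto <- identical(gamma_shape, "auto")
  shape0 <- if (auto) 1.0 else gamma_shape
  fit <- phangorn::pml(tr, dat, model = "LG", k = n_categories, shape = shape0)
  fit <- phangorn::optim.pml(fit, optNni = optimize_topology, optEdge = TRUE,
                             optGamma = auto, model = "LG",
                             control = phangorn::pml.control(trace = 0))
  structure(list(tree = fit$tree, log_likelihood = as.numeric(stats::logLik(fit)),
                 alpha = fit$shape, n_categories = as.integer(n_categories),
                 fit = fit, aln = aln),
            class = "ml_fit")
}

#' @export
print.ml_fit <- function(x, ...) {
  cat(sprintf("ML tree: %d tips, logLik %.3f, LG+G(alpha = %.3f, %d categories)\n",
              length(x$tree$tip.label), x$log_likelihood, x$alpha,
              x$n_categories))
  invisible(x)
}

# canonical string form of the bipartition induced by the edge above `node`:
# the side not containing the alphabetically first tip, sorted
bipartition_of_node <- function(tree, node) {
  n <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  tips <- ape::extract.clade(tree, node)$tip.label
  if (anchor %in% tips) tips <- setdiff(tree$tip.label, tips)
  paste(sort(tips), collapse = "|")
}

#' aLRT branch supports
#'
#' Approximate likelihood-ratio test for every internal branch of an
#' optimized ML tree. For each branch the statistic is
#' `2 (l_best - l_second)`, where `l_second` is the better of the branch's
#' two NNI alternatives after re-optimizing branch lengths, and the support
#' is `1 - p` under the `0.5 chi2_0 + 0.5 chi2_1` mixture. Supports are
#' stored as node labels of the returned tree (PhyML convention).
#'
#' @param ml an [ml_tree()] fit (topology assumed at a local NNI optimum).
#' @return the fit's tree with numeric aLRT supports in `$node.label`
#'   (`NA` for the root pseudo-node).
#' @export
alrt_support <- function(ml) {
  stopifnot(inherits(ml, "ml_fit"))
  tree <- ml$tree
  n <- length(tree$tip.label)
  dat <- as_phydat(ml$aln)
  l_best <- ml$log_likelihood
  orig_splits <- tree_split_set(tree)
  # likelihood of each NNI neighbour, edge lengths re-optimized
  nbs <- phangorn::nni(tree)
  l_nb <- numeric(length(nbs))
  changed <- character(length(nbs))
  for (i in seq_along(nbs)) {
    nb <- nbs[[i]]
    nb$edge.length[nb$edge.length < 1e-8] <- 1e-8
    f <- phangorn::pml(nb, dat, model = "LG", k = ml$n_categories,
                       shape = ml$alpha)
    f <- phangorn::optim.pml(f, optEdge = TRUE, model = "LG",
                             control = phangorn::pml.control(trace = 0))
    l_nb[i] <- as.numeric(stats::logLik(f))
    miss <- setdiff(orig_splits, tree_split_set(nb))
    changed[i] <- if (length(miss) == 1L) miss else NA_character_
  }
  node_support <- rep(NA_real_, tree$Nnode)
  root <- n + 1L
  for (nd in (n + 1L):(n + tree$Nnode)) {
    if (nd == root) next
    sp <- bipartition_of_node(tree, nd)
    if (!sp %in% orig_splits) next  # trivial split (shouldn't happen)
    ls <- l_nb[!is.na(changed) & changed == sp]
    if (!length(ls)) next
    stat <- max(0, 2 * (l_best - max(ls)))
    p <- 0.5 * (stat <= 0) + 0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
    node_support[nd - n] <- 1 - p
  }
  tree$node.label <- ifelse(is.na(node_support), "",
                            sprintf("%.6g", node_support))
  tree
}

# set of non-trivial splits of an unrooted tree, canonical strings
tree_split_set <- function(tree) {
  n <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- character(0)
  for (p in pp) {
    tips <- labs[p]
    if (anchor %in% tips) tips <- setdiff(labs, tips)
    if (length(tips) >= 2L && length(tips) <= n - 2L)
      out <- c(out, paste(sort(tips), collapse = "|"))
  }
  unique(out)
}

#' Collapse poorly supported branches
#'
#' Contracts every internal branch whose support (numeric node label of its
#' child node) is strictly below `threshold`, producing a multifurcating
#' tree; the collapsed branch's length is dropped, everything else is
#' untouched. Idempotent.
#'
#' @param tree `phylo` with numeric supports in `$node.label` (empty or `NA`
#'   labels are never collapsed).
#' @param threshold support threshold (default 0.6, the survey's value).
#' @return `phylo`, possibly multifurcating.
#' @export
collapse_low_support <- function(tree, threshold = 0.6) {
  n <- length(tree$tip.label)
  if (is.null(tree$node.label)) return(tree)
  support <- suppressWarnings(as.numeric(tree$node.label))
  children <- split(tree$edge[, 2], tree$edge[, 1])
  elen <- setNames(tree$edge.length, tree$edge[, 2])
  root <- n + 1L
  frag <- function(node) {
    # newick fragment(s) for `node` as seen from its parent, ":len" included
    if (node <= n) return(sprintf("%s:%.10g", tree$tip.label[node], elen[[as.character(node)]]))
    sub <- unlist(lapply(children[[as.character(node)]], frag))
    sup <- support[node - n]
    collapse <- !is.na(sup) && sup < threshold
    if (collapse) return(sub)  # hoist children into the parent
    lab <- tree$node.label[node - n]
    sprintf("(%s)%s:%.10g", paste(sub, collapse = ","),
            if (is.na(lab) || !nzchar(lab)) "" else lab,
            elen[[as.character(node)]])
  }
  sub <- unlist(lapply(children[[as.character(root)]], frag))
  rootlab <- tree$node.label[1]
  txt <- sprintf("(%s)%s;", paste(sub, collapse = ","),
                 if (is.na(rootlab) || !nzchar(rootlab)) "" else rootlab)
  ape::read.tree(text = txt)
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest tip-to-tip path
#' (delegated to [phangorn::midpoint()]).
#'
#' @param tree `phylo` with >= 2 tips.
#' @return rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  stopifnot(length(tree$tip.label) >= 2L)
  phangorn::midpoint(tree)
}

#' Monophyly of a tip subset
#'
#' TRUE iff some clade of the (rooted) tree contains exactly the given tips
#' (delegated to [ape::is.monophyletic()]). The full tip set and singletons
#' are trivially monophyletic.
#'
#' @param tree rooted `phylo`.
#' @param tips character vector of tip labels.
#' @return logical.
#' @export
is_monophyletic_clade <- function(tree, tips) {
  if (!all(tips %in% tree$tip.label))
    stop("unknown tip label(s): ",
         paste(setdiff(tips, tree$tip.label), collapse = ", "), call. = FALSE)
  if (length(tips) %in% c(1L, length(tree$tip.label))) return(TRUE)
  ape::is.monophyletic(tree, tips)
}

#' Bootstrap bipartition support
#'
#' Resamples alignment columns with replacement, re-infers a tree per
#' replicate (NJ start, branch-length optimization, optional NNI), and
#' reports for each internal branch of `ml$tree` the fraction of replicate
#' trees containing its bipartition.
#'
#' @param ml an [ml_tree()] fit.
#' @param n_replicates bootstrap replicates (default 100).
#' @param seed integer seed.
#' @param optimize_topology NNI search within replicates (default TRUE).
#' @return the fit's tree with bootstrap proportions in `$node.label`.
#' @export
bootstrap_support <- function(ml, n_replicates = 100L, seed = 1L,
                              optimize_topology = TRUE) {
  stopifnot(inherits(ml, "ml_fit"))
  aln <- ml$aln
  L <- nchar(aln[[1]])
  mat <- do.call(rbind, strsplit(aln, ""))
  trees <- withr::with_seed(seed, {
    lapply(seq_len(n_replicates), function(b) {
      cols <- sample.int(L, L, replace = TRUE)
      bal <- setNames(apply(mat[, cols, drop = FALSE], 1, paste, collapse = ""),
                      names(aln))
      ml_tree(bal, gamma_shape = ml$alpha, n_categories = ml$n_categories,
              optimize_topology = optimize_topology)$tree
    })
  })
  ref <- ml$tree
  n <- length(ref$tip.label)
  counts <- vapply((n + 1L):(n + ref$Nnode), function(nd) {
    sp <- bipartition_of_node(ref, nd)
    sum(vapply(trees, function(tr) sp %in% tree_split_set(tr), TRUE))
  }, 1)
  props <- counts / n_replicates
  props[1] <- NA  # root pseudo-node
  ref$node.label <- ifelse(is.na(props), "", sprintf("%.6g", props))
  ref
}

#' Robinson-Foulds distance
#'
#' Thin wrapper over [phangorn::RF.dist()] used by the recovery benchmarks.
#'
#' @param t1,t2 `phylo` trees on the same tips.
#' @return integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  phangorn::RF.dist(t1, t2)
}
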