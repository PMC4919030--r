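mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(protein_id = r$p %||% "p1", profile_id = r$id,
               evalue = r$e, env_start = r$s, env_end = r$t,
               stringsAsFactors = FALSE)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("lower expect value wins an overlap; non-overlapping hits all pass", {
  hits <- mk_hits(list(id = "A", e = 1e-10, s = 1, t = 100),
                  list(id = "B", e = 1e-5, s = 51, t = 150))
  res <- resolve_overlaps(hits, protein_length = 150)
  expect_identical(res$accepted$profile_id, "A")
  expect_identical(res$rejected$profile_id, "B")
  hits2 <- mk_hits(list(id = "B", e = 1e-4, s = 120, t = 200),
                   list(id = "A", e = 1e-8, s = 1, t = 100))
  res2 <- resolve_overlaps(hits2, protein_length = 200)
  expect_identical(res2$accepted$profile_id, c("A", "B"))  # sorted by start
  expect_identical(nrow(res2$rejected), 0L)
  expect_error(resolve_overlaps(mk_hits(list(id = "A", e = 1, s = 1, t = 5,
                                             p = "x"),
                                        list(id = "B", e = 1, s = 1, t = 5,
                                             p = "y"))),
               "one protein")
})

test_that("greedy resolution matches an independent second implementation", {
  for (i in 1:1000) {
    hits <- random_hit_set(sample(1:8, 1), seed = i)
    got <- resolve_overlaps(hits, protein_length = 300)$accepted
    want <- resolve_overlaps_oracle(hits)
    expect_identical(got$env_start, want$env_start, info = paste("case", i))
    expect_identical(got$profile_id, want$profile_id, info = paste("case", i))
  }
})

test_that("every hit is accepted or rejected, accepted never overlap, order-invariant", {
  for (i in 1:50) {
    hits <- random_hit_set(6, seed = 5000 + i)
    res <- resolve_overlaps(hits, protein_length = 300)
    expect_identical(nrow(res$accepted) + nrow(res$rejected), nrow(hits))
    acc <- res$accepted
    if (nrow(acc) > 1)
      for (a in 1:(nrow(acc) - 1))
        expect_lt(acc$env_end[a], acc$env_start[a + 1])
    perm <- hits[withr::with_seed(i, sample(nrow(hits))), , drop = FALSE]
    res2 <- resolve_overlaps(perm, protein_length = 300)
    expect_identical(res$accepted$env_start, res2$accepted$env_start)
  }
})

test_that("terminus classes follow the orphan-aware rule", {
  # [MCP_signal, Hr]: focal domain is C-terminal
  ann <- resolve_overlaps(mk_hits(list(id = "MCP_signal", e = 1e-9, s = 1, t = 150),
                                  list(id = "Hr", e = 1e-8, s = 160, t = 270)),
                          protein_length = 280)
  expect_identical(terminus_class(ann, "Hr"), "C-terminal")
  expect_identical(terminus_class(ann, "MCP_signal"), "N-terminal")
  # [Hr, GGDEF]: focal domain is N-terminal
  ann2 <- resolve_overlaps(mk_hits(list(id = "Hr", e = 1e-8, s = 5, t = 120),
                                   list(id = "GGDEF", e = 1e-7, s = 130, t = 290)),
                           protein_length = 300)
  expect_identical(terminus_class(ann2, "Hr"), "N-terminal")
  # [Hr] alone with high coverage: only-domain
  ann3 <- resolve_overlaps(mk_hits(list(id = "Hr", e = 1e-8, s = 3, t = 118)),
                           protein_length = 120)
  expect_identical(terminus_class(ann3, "Hr"), "only-domain")
  # an orphan elongation before the domain demotes N-terminal to internal-ish
  ann4 <- resolve_overlaps(mk_hits(list(id = "X", e = 1e-6, s = 200, t = 300),
                                   list(id = "Hr", e = 1e-9, s = 81, t = 190)),
                           protein_length = 310)
  expect_identical(nrow(ann4$orphan_regions), 1L)  # residues 1..80
  expect_identical(terminus_class(ann4, "Hr"), "internal")
  expect_error(terminus_class(ann3, "GGDEF"), "not in the accepted set")
  # each focal hit gets exactly one class
  for (a in list(ann, ann2, ann3, ann4))
    expect_identical(length(terminus_class(a, "Hr")), 1L)
})

test_that("catalogs conserve totals and ignore input order", {
  anns <- list(
    resolve_overlaps(mk_hits(list(id = "Hr", e = 1e-9, s = 1, t = 118, p = "a")),
                     protein_length = 120),
    resolve_overlaps(mk_hits(list(id = "Hr", e = 1e-9, s = 1, t = 118, p = "b")),
                     protein_length = 120),
    resolve_overlaps(mk_hits(list(id = "MCP", e = 1e-9, s = 1, t = 150, p = "c"),
                             list(id = "Hr", e = 1e-8, s = 170, t = 280, p = "c")),
                     protein_length = 290))
  smap <- c(a = "sp1", b = "sp1", c = "sp2")
  cat1 <- architecture_catalog(anns, smap)
  expect_identical(sum(cat1$count), 3L)
  cat_perm <- architecture_catalog(rev(anns), smap)
  expect_identical(cat1, cat_perm, ignore_attr = TRUE)
  # one architecture only -> single all-ones column over its species
  solo <- architecture_catalog(anns[1:2], smap)
  pa <- presence_absence(solo)
  expect_identical(dim(pa), c(1L, 1L))
  expect_identical(unname(pa[1, 1]), 1L)
  # species errors are configurable
  expect_error(architecture_catalog(anns, c(a = "sp1")), "missing")
  cat2 <- architecture_catalog(anns, c(a = "sp1"), missing_species = "unknown")
  expect_true("unknown" %in% unlist(attr(cat2, "by_species")))
})

test_that("copy numbers count single and long focal proteins per species", {
  mk_single <- function(p) resolve_overlaps(
    mk_hits(list(id = "Hr", e = 1e-9, s = 1, t = 118, p = p)),
    protein_length = 125)
  mk_long <- function(p) resolve_overlaps(
    mk_hits(list(id = "Hr", e = 1e-9, s = 201, t = 318, p = p)),
    protein_length = 320)
  # emulate one species with 15 single-domain paralogs (and 2 long elsewhere)
  anns <- c(lapply(sprintf("mag%02d", 1:15), mk_single),
            lapply(c("oth1", "oth2"), mk_long))
  smap <- c(setNames(rep("M_magneticum", 15), sprintf("mag%02d", 1:15)),
            oth1 = "other", oth2 = "other")
  tab <- copy_number_table(anns, "Hr", smap)
  expect_identical(tab$single_domain[tab$species == "M_magneticum"], 15L)
  expect_identical(tab$long[tab$species == "other"], 2L)
  expect_identical(sum(tab$single_domain) + sum(tab$long), 17L)
})

test_that("function summary reports proportions over accepted non-focal domains", {
  # fixture mirroring a 43% signal-transduction share
  mk <- function(p, id) resolve_overlaps(
    mk_hits(list(id = id, e = 1e-9, s = 1, t = 100, p = p),
            list(id = "Hr", e = 1e-8, s = 120, t = 237, p = p)),
    protein_length = 240)
  doms <- c(rep("MCP_signal", 43), rep("Response_reg", 7), rep("SH3", 6),
            rep("NoMap", 44))
  anns <- lapply(seq_along(doms), function(i) mk(paste0("p", i), doms[i]))
  fmap <- default_function_map()
  fs <- function_summary(anns, fmap, focal_profile = "Hr")
  expect_identical(fs$total, 100L)
  expect_equal(unname(fs$proportions["signal transduction"]), 0.43)
  expect_equal(unname(fs$proportions["phosphorelay response regulation"]), 0.07)
  expect_equal(unname(fs$proportions["protein binding"]), 0.06)
  expect_identical(fs$unmapped, 44L)
  expect_lte(sum(fs$proportions), 1)
  # all mapped to one category -> proportion 1; empty map -> all unmapped
  one <- function_summary(anns[1:3], c(MCP_signal = "signal transduction"), "Hr")
  expect_equal(unname(one$proportions), 1)
  none <- function_summary(anns[1:3], c(other = "x"), "Hr")
  expect_identical(length(none$proportions), 0L)
  expect_identical(none$unmapped, 3L)
})
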