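#' Pipeline configuration
#'
#' All stage parameters of the end-to-end survey with their reference
#' defaults: 200 shuffles, BLOSUM50 with -10/-2, homolog cutoff E < 1e-3,
#' seed-collection E < 1e-5 with reference coverage > 95%, protein-coverage
#' split at 85%, anchor weight 5, 6 gamma categories, aLRT collapse at 0.6.
#' Configs round-trip losslessly through JSON; unknown keys are rejected.
#'
#' @param ... overrides of the defaults listed above.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_proteins = 120L, planting_rate = 0.35,
    divergence_range = c(0.1, 0.8),
    n_shuffles = 200L, matrix_name = "BLOSUM50",
    gap_open = -10L, gap_extend = -2L,
    homolog_expect = 1e-3,
    seed_expect = 1e-5, seed_reference_coverage = 0.95,
    protein_coverage = 0.85,
    anchor_weight = 5.0, match_rule = 0.5, pseudocount = 1.0,
    scan_expect = 1e-3, calibration_n = 500L,
    min_orphan = 50L,
    gamma_shape = "auto", n_categories = 6L, collapse_threshold = 0.6,
    run_alrt = TRUE, max_tree_tips = 30L,
    master_seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration:\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k,
                                  paste(format(x[[k]]), collapse = " ")))
  invisible(x)
}

# per-stage seeds fan out from the master seed by stage index
stage_seed <- function(cfg, stage) derive_seed(cfg$master_seed, stage)

#' Run the full survey pipeline on a synthetic proteome
#'
#' Executes the stages in order: simulate a proteome with planted domain
#' families; collect seed sequences by pairwise homology to reference
#' queries; align them; build the anchored profile HMM; calibrate its
#' E-value null; scan the proteome; classify and resolve architectures;
#' align the single-domain hits and infer the ML tree (aLRT supports,
#' collapse, midpoint rooting); tabulate reports. Every output file is
#' checksummed into the run manifest; a rerun with the same config is
#' byte-identical (wall-time aside).
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return object of class `run_manifest`: list with `config`, `files`
#'   (data.frame path/md5), `stages` (named list of per-stage summaries),
#'   `warnings`, `wall_time`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = tempfile("hrsurvey_")) {
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warn <- character(0)
  stages <- list()
  scheme <- scoring_scheme(cfg$matrix_name, cfg$gap_open, cfg$gap_extend)

  # -- simulate
  tpl <- make_default_templates(seed = stage_seed(cfg, 1L))
  templates <- c(list(tpl$hemerythrin, tpl$sister_hhe), tpl$decoys)
  prot <- generate_proteome(templates, default_architectures(),
                            n_proteins = cfg$n_proteins,
                            planting_rate = cfg$planting_rate,
                            divergence_range = cfg$divergence_range,
                            seed = stage_seed(cfg, 2L))
  write_fasta(prot$proteins, file.path(out_dir, "proteome.fasta"))
  write_truth_tsv(prot, file.path(out_dir, "truth.tsv"))
  stages$simulate <- list(n_proteins = length(prot$proteins),
                          n_planted = nrow(prot$truth))

  # -- seed collection against near-consensus references
  refs <- c(ref1 = mutate_from_template(tpl$hemerythrin, 0.05,
                                        seed = stage_seed(cfg, 3L)),
            ref2 = mutate_from_template(tpl$hemerythrin, 0.05,
                                        seed = stage_seed(cfg, 4L)))
  seeds <- withCallingHandlers(
    collect_seed(refs, prot, expect_cutoff = cfg$seed_expect,
                 coverage_cutoff = cfg$seed_reference_coverage,
                 scheme = scheme, n_shuffles = cfg$n_shuffles,
                 seed = stage_seed(cfg, 5L)),
    warning = function(w) { warn <<- c(warn, conditionMessage(w))
                            invokeRestart("muffleWarning") })
  stages$collect_seed <- list(n_seed = length(seeds))
  if (length(seeds) < 2L) {
    manifest <- finish_manifest(cfg, out_dir, stages,
                                c(warn, "too few seed sequences; downstream stages skipped"),
                                t0)
    return(manifest)
  }

  # -- seed alignment and profile HMM
  seed_aln <- progressive_align(seeds, scheme)
  write_alignment(seed_aln, file.path(out_dir, "seed.afa"))
  anchors <- anchor_columns(seed_aln, tpl$hemerythrin, weight = cfg$anchor_weight)
  hmm <- build_phmm(seed_aln, match_rule = cfg$match_rule,
                    pseudocount = cfg$pseudocount, anchors = anchors,
                    profile_id = "hemerythrin")
  write_phmm(hmm, file.path(out_dir, "hemerythrin.phmm"))
  stages$build_phmm <- list(node_count = hmm$node_count,
                            n_anchor = if (is.null(hmm$anchor_nodes)) 0L
                                       else nrow(hmm$anchor_nodes))

  # -- calibrate and scan
  calib <- calibrate_evalue(hmm, n_random = cfg$calibration_n,
                            length = 300L, seed = stage_seed(cfg, 6L))
  hits <- scan_proteome(hmm, prot, calibration = calib,
                        evalue_cutoff = cfg$scan_expect, multihit = TRUE)
  write_hits_tsv(hits, file.path(out_dir, "hits.tsv"))
  stages$scan <- list(n_hits = nrow(hits))

  # -- architecture resolution
  annotations <- list()
  if (nrow(hits)) {
    for (id in unique(hits$protein_id)) {
      h <- hits[hits$protein_id == id, , drop = FALSE]
      annotations[[id]] <- resolve_overlaps(h, nchar(prot$proteins[[id]]),
                                            min_orphan = cfg$min_orphan)
    }
  }
  species_map <- setNames(rep(prot$species_id, length(prot$proteins)),
                          names(prot$proteins))
  if (length(annotations)) {
    cat_tab <- architecture_catalog(annotations, species_map)
    copies <- copy_number_table(annotations, "hemerythrin", species_map,
                                coverage_threshold = cfg$protein_coverage)
    pa <- presence_absence(cat_tab)
    write.table(cat_tab, file.path(out_dir, "architectures.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(copies, file.path(out_dir, "copies.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(pa, file.path(out_dir, "presence_absence.tsv"), sep = "\t",
                quote = FALSE, col.names = NA)
    stages$architect <- list(n_architectures = nrow(cat_tab))
  } else stages$architect <- list(n_architectures = 0L)

  # -- phylogeny of single-domain hits
  singles <- hits[hits$classification == "single_domain", , drop = FALSE]
  if (nrow(singles) >= 4L) {
    ids <- utils::head(unique(singles$protein_id), cfg$max_tree_tips)
    doms <- vapply(ids, function(id) {
      h <- singles[singles$protein_id == id, , drop = FALSE][1, ]
      substr(prot$proteins[[id]], h$env_start, h$env_end)
    }, "")
    dom_aln <- progressive_align(setNames(doms, ids), scheme)
    write_alignment(dom_aln, file.path(out_dir, "single_domain.afa"))
    ml <- ml_tree(dom_aln, gamma_shape = cfg$gamma_shape,
                  n_categories = cfg$n_categories)
    tree <- if (cfg$run_alrt) alrt_support(ml) else ml$tree
    if (cfg$run_alrt) tree <- collapse_low_support(tree, cfg$collapse_threshold)
    tree <- midpoint_root(tree)
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
    stages$tree <- list(n_tips = length(tree$tip.label),
                        log_likelihood = ml$log_likelihood, alpha = ml$alpha)
  } else {
    stages$tree <- list(n_tips = 0L)
    warn <- c(warn, "fewer than 4 single-domain hits; tree stage skipped")
  }
  finish_manifest(cfg, out_dir, stages, warn, t0)
}

finish_manifest <- function(cfg, out_dir, stages, warn, t0) {
  files <- list.files(out_dir, full.names = TRUE)
  manifest <- structure(
    list(config = cfg,
         files = data.frame(path = basename(files),
                            md5 = unname(tools::md5sum(files)),
                            stringsAsFactors = FALSE),
         stages = stages, warnings = warn,
         wall_time = as.numeric(Sys.time() - t0, units = "secs"),
         out_dir = out_dir),
    class = "run_manifest")
  jsonlite::write_json(
    list(config = unclass(cfg), files = manifest$files, stages = stages,
         warnings = warn),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Pipeline run (%.1f s): %d output files in %s\n", x$wall_time,
              nrow(x$files), x$out_dir))
  for (s in names(x$stages))
    cat(sprintf("  %-14s %s\n", s,
                paste(names(x$stages[[s]]), unlist(x$stages[[s]]),
                      sep = "=", collapse = "  ")))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Locate template anchor residues in a seed alignment
#'
#' Maps the anchor positions of a template to alignment columns by majority
#' residue agreement: a column is called an anchor when the template's
#' anchor residue is its most frequent residue and the column's occupancy
#' is at least 0.5. Used by [run_pipeline()] to re-anchor the profile HMM
#' without looking at the simulation truth.
#'
#' @param aln seed alignment (named character vector).
#' @param template the focal [domain_template()].
#' @param weight anchor weight (default 5).
#' @return data.frame column/residue/weight suitable for [build_phmm()].
#' @export
anchor_columns <- function(aln, template, weight = 5.0) {
  mat <- do.call(rbind, strsplit(aln, ""))
  res <- character(0); col <- integer(0)
  want <- table(template$anchor_residues)
  for (r in names(want)) {
    scores <- vapply(seq_len(ncol(mat)), function(j) {
      cnt <- sum(mat[, j] == r)
      if (mean(mat[, j] != "-") < 0.5) 0L else cnt
    }, 0L)
    top <- order(scores, decreasing = TRUE)[seq_len(want[[r]])]
    top <- top[scores[top] > 0.5 * nrow(mat)]
    col <- c(col, top); res <- c(res, rep(r, length(top)))
  }
  if (!length(col))
    return(data.frame(column = integer(0), residue = character(0),
                      weight = numeric(0)))
  data.frame(column = col, residue = res, weight = weight,
             stringsAsFactors = FALSE)
}
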