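#' Domain templates for synthetic proteomes
#'
#' A domain template is the ancestral (consensus) sequence of a simulated
#' domain family plus a set of anchor residues — positions whose residue is
#' functionally constrained, like the five histidines, one glutamate and one
#' aspartate that coordinate the di-iron centre of oxygen-binding
#' hemerythrins.
#'
#' @param template_id label.
#' @param consensus amino-acid string (>= 20 residues, standard alphabet).
#' @param anchor_positions integer vector of 1-based positions.
#' @param anchor_residues character vector, same length, the constrained
#'   residue at each anchor.
#' @param anchor_conservation probability that an anchor survives a
#'   substitution that would otherwise occur (1 = anchors never mutate).
#' @return object of class `domain_template`.
#' @export
domain_template <- function(template_id, consensus, anchor_positions = integer(0),
                            anchor_residues = character(0),
                            anchor_conservation = 1.0) {
  n <- nchar(consensus)
  stopifnot(n >= 20L, length(anchor_positions) == length(anchor_residues),
            anchor_conservation >= 0, anchor_conservation <= 1)
  aa_encode(consensus, extra = character(0))  # validates the alphabet
  if (length(anchor_positions) &&
      (any(anchor_positions < 1L) || any(anchor_positions > n)))
    stop("anchor positions out of bounds", call. = FALSE)
  cons <- consensus
  if (length(anchor_positions)) {
    ch <- strsplit(cons, "")[[1]]
    ch[anchor_positions] <- anchor_residues
    cons <- paste(ch, collapse = "")
  }
  structure(list(template_id = template_id, length = n, consensus = cons,
                 anchor_positions = as.integer(anchor_positions),
                 anchor_residues = anchor_residues,
                 anchor_conservation = anchor_conservation),
            class = "domain_template")
}

#' @export
print.domain_template <- function(x, ...) {
  cat(sprintf("Domain template '%s': %d residues, %d anchors (%s)\n",
              x$template_id, x$length, length(x$anchor_positions),
              paste0(x$anchor_residues, x$anchor_positions, collapse = " ")))
  invisible(x)
}

#' Default template set: hemerythrin, a sister family, and decoys
#'
#' Builds the study's simulated cast: a 118-residue oxygen-binding
#' hemerythrin analogue with the canonical 7 iron-coordinating anchors
#' (5 His, 1 Glu, 1 Asp), a divergent sister family of the same fold length
#' with an altered coordination site (the HHE cation-binding analogue), and
#' unrelated decoy domains. Non-anchor consensus residues are drawn from LG
#' equilibrium frequencies; the sister family differs from the hemerythrin
#' consensus at >= 40% of positions and at >= 2 anchors.
#'
#' @param seed integer seed.
#' @return list with elements `hemerythrin`, `sister_hhe`, `decoys` (list of
#'   two templates of lengths 60 and 200).
#' @export
make_default_templates <- function(seed = 1L) {
  model <- lg_model()
  freqs <- model$frequencies
  draw <- function(n) paste(sample(AA20, n, replace = TRUE, prob = freqs),
                            collapse = "")
  # anchor layout loosely follows the helix-turn spacing of the real domain
  anchor_pos <- c(25L, 54L, 58L, 73L, 77L, 106L, 111L)
  anchor_res <- c("H", "H", "E", "H", "H", "H", "D")
  withr::with_seed(seed, {
    hr_cons <- draw(118L)
    hr <- domain_template("hemerythrin", hr_cons, anchor_pos, anchor_res,
                          anchor_conservation = 1.0)
    # sister family: resample half the non-anchor positions, swap 3 anchors
    ch <- strsplit(hr$consensus, "")[[1]]
    non_anchor <- setdiff(seq_len(118L), anchor_pos)
    flip <- sample(non_anchor, ceiling(0.5 * length(non_anchor)))
    for (i in flip) ch[i] <- sample(setdiff(AA20, ch[i]), 1L)
    sis_res <- c("H", "H", "E", "N", "Q", "H", "S")  # altered at 3 anchors
    sister <- domain_template("sister_hhe", paste(ch, collapse = ""),
                              anchor_pos, sis_res, anchor_conservation = 1.0)
    decoys <- list(domain_template("decoy_small", draw(60L)),
                   domain_template("decoy_large", draw(200L)))
  })
  list(hemerythrin = hr, sister_hhe = sister, decoys = decoys)
}

#' Mutate a sequence away from its template
#'
#' Each site is substituted with probability `1 - exp(-divergence)`; at
#' anchor positions that probability is further multiplied by
#' `1 - anchor_conservation`. The replacement residue is drawn uniformly
#' from the 19 other residues, so the expected fraction of changed sites is
#' exactly `1 - exp(-divergence)` for non-anchor positions.
#'
#' @param template a [domain_template()].
#' @param divergence expected substitutions per site (>= 0).
#' @param seed integer seed.
#' @return amino-acid string of the same length as the template.
#' @export
mutate_from_template <- function(template, divergence, seed = 1L) {
  if (!is.finite(divergence) || divergence < 0)
    stop("divergence must be >= 0", call. = FALSE)
  ch <- strsplit(template$consensus, "")[[1]]
  p <- rep(1 - exp(-divergence), template$length)
  p[template$anchor_positions] <-
    p[template$anchor_positions] * (1 - template$anchor_conservation)
  withr::with_seed(seed, {
    hit <- runif(template$length) < p
    for (i in which(hit)) ch[i] <- sample(setdiff(AA20, ch[i]), 1L)
  })
  paste(ch, collapse = "")
}

#' Architecture specifications
#'
#' An architecture spec is an ordered list of segment descriptors, each a
#' list with `kind` (`"domain"`, `"linker"` or `"orphan"`) and either
#' `template` (a template id, for domains) or `mean_length` (for
#' linker/orphan segments, geometric length distribution). Linkers model
#' short inter-domain connectors; orphans model the long terminal
#' elongations with no domain assignment seen in real long hemerythrin
#' proteins.
#'
#' @param ... segment descriptors.
#' @return object of class `architecture_spec`.
#' @export
architecture_spec <- function(...) {
  segs <- list(...)
  stopifnot(length(segs) >= 1L)
  for (s in segs) {
    stopifnot(s$kind %in% c("domain", "linker", "orphan"))
    if (s$kind == "domain") stopifnot(!is.null(s$template))
    else stopifnot(s$mean_length >= 0)
  }
  structure(segs, class = "architecture_spec")
}

#' Default architecture mix
#'
#' Emulates the dominant layouts of the real survey: single-domain
#' hemerythrins, an N-terminal signalling domain with C-terminal hemerythrin
#' (the MCP-like layout), hemerythrin followed by a cyclase-like domain
#' (the GGDEF-like layout), and hemerythrin with an orphan elongation.
#'
#' @param focal template id of the focal domain.
#' @param decoy_ids template ids usable as fused partner domains.
#' @return named list of [architecture_spec()] objects.
#' @export
default_architectures <- function(focal = "hemerythrin",
                                  decoy_ids = c("decoy_small", "decoy_large")) {
  dom <- function(id) list(kind = "domain", template = id)
  link <- function(m = 30) list(kind = "linker", mean_length = m)
  orph <- function(m = 80) list(kind = "orphan", mean_length = m)
  list(single = architecture_spec(dom(focal)),
       partner_focal = architecture_spec(dom(decoy_ids[1]), link(), dom(focal)),
       focal_partner = architecture_spec(dom(focal), link(), dom(decoy_ids[2])),
       orphan_focal = architecture_spec(orph(), dom(focal)))
}

#' Generate a seeded synthetic proteome with planted domains
#'
#' Every protein either carries planted domains realized from a sampled
#' architecture spec (recorded in the truth table) or is a pure background
#' sequence drawn from LG equilibrium frequencies. Deterministic given the
#' seed.
#'
#' @param templates named list of [domain_template()] objects (every template
#'   referenced by `architectures` must be present).
#' @param architectures list of [architecture_spec()] objects sampled
#'   uniformly for planted proteins.
#' @param n_proteins number of proteins (>= 1).
#' @param planting_rate probability a protein carries planted domains.
#' @param divergence_range range of per-domain divergences, drawn uniformly.
#' @param background_length mean length of background proteins (geometric,
#'   shifted by 50 so every protein has at least 50 residues).
#' @param species_id label for the proteome.
#' @param seed integer seed.
#' @return object of class `synthetic_proteome`: list with `species_id`,
#'   `proteins` (named character vector) and `truth` (data.frame protein_id,
#'   template_id, start, end, divergence; 1-based closed intervals).
#' @export
generate_proteome <- function(templates, architectures = default_architectures(),
                              n_proteins = 100L, planting_rate = 0.5,
                              divergence_range = c(0.1, 1.5),
                              background_length = 250, species_id = "synthetic",
                              seed = 1L) {
  if (!length(templates)) stop("empty template list", call. = FALSE)
  if (n_proteins < 1L) stop("n_proteins must be >= 1", call. = FALSE)
  if (planting_rate < 0 || planting_rate > 1)
    stop("planting_rate must be in [0, 1]", call. = FALSE)
  names(templates) <- vapply(templates, `[[`, "", "template_id")
  model <- lg_model()
  freqs <- model$frequencies
  proteins <- character(n_proteins)
  ids <- sprintf("%s_p%04d", species_id, seq_len(n_proteins))
  truth <- vector("list", n_proteins)
  withr::with_seed(seed, {
    for (i in seq_len(n_proteins)) {
      if (runif(1) < planting_rate) {
        spec <- architectures[[sample(length(architectures), 1L)]]
        segs <- character(0)
        recs <- list()
        pos <- 0L
        for (s in spec) {
          if (s$kind == "domain") {
            tpl <- templates[[s$template]]
            if (is.null(tpl)) stop("unknown template: ", s$template,
                                   call. = FALSE)
            d <- runif(1, divergence_range[1], divergence_range[2])
            seqs <- mutate_from_template(tpl, d,
                                         seed = sample.int(2^31 - 2, 1L))
            recs[[length(recs) + 1L]] <-
              data.frame(protein_id = ids[i], template_id = tpl$template_id,
                         start = pos + 1L, end = pos + tpl$length,
                         divergence = d, stringsAsFactors = FALSE)
            segs <- c(segs, seqs)
            pos <- pos + tpl$length
          } else {
            len <- rgeom(1, 1 / (s$mean_length + 1))
            seg <- if (len > 0)
              paste(sample(AA20, len, replace = TRUE, prob = freqs),
                    collapse = "") else ""
            segs <- c(segs, seg)
            pos <- pos + len
          }
        }
        proteins[i] <- paste(segs, collapse = "")
        truth[[i]] <- if (length(recs)) do.call(rbind, recs) else NULL
      } else {
        len <- 50L + rgeom(1, 1 / background_length)
        proteins[i] <- paste(sample(AA20, len, replace = TRUE, prob = freqs),
                             collapse = "")
      }
    }
  })
  names(proteins) <- ids
  truth <- do.call(rbind, truth[!vapply(truth, is.null, TRUE)])
  if (is.null(truth))
    truth <- data.frame(protein_id = character(0), template_id = character(0),
                        start = integer(0), end = integer(0),
                        divergence = numeric(0), stringsAsFactors = FALSE)
  structure(list(species_id = species_id, proteins = proteins, truth = truth),
            class = "synthetic_proteome")
}

#' @export
print.synthetic_proteome <- function(x, ...) {
  cat(sprintf("Synthetic proteome '%s': %d proteins, %d planted domains\n",
              x$species_id, length(x$proteins), nrow(x$truth)))
  invisible(x)
}

#' Write the planted-domain truth table
#'
#' The file uses 0-based half-open coordinates (columns `start`, `end`);
#' in-memory truth tables are 1-based closed. [read_truth_tsv()] converts
#' back.
#'
#' @param proteome a [generate_proteome()] result (or its `truth` field).
#' @param path output path.
#' @export
write_truth_tsv <- function(proteome, path) {
  truth <- if (inherits(proteome, "synthetic_proteome")) proteome$truth
           else proteome
  out <- truth
  out$start <- out$start - 1L  # to 0-based half-open
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  truth <- read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  truth$start <- truth$start + 1L  # back to 1-based closed
  truth
}
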