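#' Resolve overlapping domain hits on one protein
#'
#' Greedy acceptance in ascending E-value order ("prefer domains with lower
#' expect values"): a hit is rejected iff its envelope shares at least one
#' residue with an already-accepted hit (no tolerance window by default).
#' Ties on E-value are broken by longer envelope, then lexicographic
#' profile_id. Unannotated stretches of at least `min_orphan` residues are
#' reported as orphan regions.
#'
#' @param hits data.frame with columns protein_id, profile_id, evalue,
#'   env_start, env_end (1-based closed), all on one protein.
#' @param protein_length protein length in residues (default: max env_end).
#' @param min_orphan minimum length for an unannotated region to count as an
#'   orphan elongation (default 50).
#' @param overlap_tolerance residues of overlap tolerated between accepted
#'   envelopes (default 0, the strict rule).
#' @return object of class `domain_annotation`: list with `protein_id`,
#'   `protein_length`, `accepted` (data.frame ordered by env_start),
#'   `rejected`, `orphan_regions` (data.frame start/end).
#' @export
resolve_overlaps <- function(hits, protein_length = NULL, min_orphan = 50L,
                             overlap_tolerance = 0L) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) && length(unique(hits$protein_id)) > 1L)
    stop("hits span multiple proteins; resolve one protein at a time",
         call. = FALSE)
  protein_length <- protein_length %||%
    (if (nrow(hits)) max(hits$env_end) else 0L)
  ord <- order(hits$evalue, -(hits$env_end - hits$env_start), hits$profile_id)
  hits <- hits[ord, , drop = FALSE]
  acc <- rep(FALSE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ov <- FALSE
    for (j in which(acc)) {
      shared <- min(hits$env_end[i], hits$env_end[j]) -
        max(hits$env_start[i], hits$env_start[j]) + 1L
      if (shared > overlap_tolerance) { ov <- TRUE; break }
    }
    acc[i] <- !ov
  }
  accepted <- hits[acc, , drop = FALSE]
  accepted <- accepted[order(accepted$env_start), , drop = FALSE]
  rownames(accepted) <- NULL
  rejected <- hits[!acc, , drop = FALSE]
  rownames(rejected) <- NULL
  # orphan regions: maximal uncovered intervals of length >= min_orphan
  orphans <- data.frame(start = integer(0), end = integer(0))
  cursor <- 1L
  bounds <- rbind(accepted[, c("env_start", "env_end")],
                  data.frame(env_start = protein_length + 1L,
                             env_end = protein_length + 1L))
  for (i in seq_len(nrow(bounds))) {
    gap_end <- bounds$env_start[i] - 1L
    if (gap_end - cursor + 1L >= min_orphan)
      orphans <- rbind(orphans, data.frame(start = cursor, end = gap_end))
    cursor <- max(cursor, bounds$env_end[i] + 1L)
  }
  structure(list(protein_id = if (nrow(hits)) hits$protein_id[1] else NA_character_,
                 protein_length = protein_length, accepted = accepted,
                 rejected = rejected, orphan_regions = orphans,
                 min_orphan = min_orphan),
            class = "domain_annotation")
}

#' @export
print.domain_annotation <- function(x, ...) {
  cat(sprintf("Annotation of %s (%d aa): %s\n", x$protein_id,
              x$protein_length, architecture_string(x)))
  invisible(x)
}

#' Architecture string of a resolved annotation
#'
#' Ordered tokens: accepted domain names with `ORPHAN` markers interleaved
#' at orphan regions.
#'
#' @param annotation a [resolve_overlaps()] result.
#' @return character scalar like `"MCP_signal+hemerythrin"` or
#'   `"ORPHAN+hemerythrin"`.
#' @export
architecture_string <- function(annotation) {
  items <- rbind(
    if (nrow(annotation$accepted))
      data.frame(pos = annotation$accepted$env_start,
                 tok = annotation$accepted$profile_id),
    if (nrow(annotation$orphan_regions))
      data.frame(pos = annotation$orphan_regions$start, tok = "ORPHAN"))
  if (is.null(items) || !nrow(items)) return("")
  paste(items$tok[order(items$pos)], collapse = "+")
}

#' Terminus class of the focal domain
#'
#' Where does the focal domain sit in the protein? `N-terminal` iff no
#' accepted domain and no orphan region precedes it; `C-terminal` iff none
#' follows; `only-domain` when both hold; `internal` otherwise. When the
#' focal profile was accepted more than once the first occurrence is
#' classified.
#'
#' @param annotation a [resolve_overlaps()] result.
#' @param focal_profile profile id of the focal domain.
#' @return one of `"N-terminal"`, `"C-terminal"`, `"internal"`,
#'   `"only-domain"`.
#' @export
terminus_class <- function(annotation, focal_profile) {
  acc <- annotation$accepted
  k <- which(acc$profile_id == focal_profile)
  if (!length(k))
    stop("focal profile '", focal_profile, "' not in the accepted set",
         call. = FALSE)
  k <- k[1]
  before <- sum(acc$env_start < acc$env_start[k]) +
    sum(annotation$orphan_regions$start < acc$env_start[k])
  after <- sum(acc$env_start > acc$env_start[k]) +
    sum(annotation$orphan_regions$start > acc$env_start[k])
  if (before == 0L && after == 0L) "only-domain"
  else if (before == 0L) "N-terminal"
  else if (after == 0L) "C-terminal"
  else "internal"
}

#' Architecture catalog, copy numbers, presence/absence, function summary
#'
#' Report operations over a list of resolved annotations:
#' `architecture_catalog()` counts architecture strings and records which
#' species show them; `copy_number_table()` counts single-domain and long
#' focal-domain proteins per species; `presence_absence()` renders the
#' catalog as a binary architectures x species matrix; `function_summary()`
#' maps accepted non-focal domains to functional categories and reports
#' proportions.
#'
#' @param annotations list of [resolve_overlaps()] results.
#' @param species_map named character vector protein_id -> species_id.
#' @param missing_species `"error"` or `"unknown"` (bucket unmapped proteins
#'   under "unknown").
#' @return `architecture_catalog()`: data.frame architecture, count,
#'   species (comma-joined), plus `attr(, "by_species")`.
#' @export
architecture_catalog <- function(annotations, species_map = NULL,
                                 missing_species = c("error", "unknown")) {
  missing_species <- match.arg(missing_species)
  archs <- vapply(annotations, architecture_string, "")
  ids <- vapply(annotations, `[[`, "", "protein_id")
  sp <- species_of(ids, species_map, missing_species)
  tab <- table(archs)
  by_species <- split(sp, archs)
  out <- data.frame(architecture = names(tab), count = as.integer(tab),
                    species = vapply(by_species[names(tab)], function(s)
                      paste(sort(unique(s)), collapse = ","), ""),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$count, out$architecture), ]
  rownames(out) <- NULL
  attr(out, "by_species") <- lapply(by_species, function(s) sort(unique(s)))
  out
}

species_of <- function(ids, species_map, missing_species) {
  if (is.null(species_map)) return(rep("unknown", length(ids)))
  sp <- unname(species_map[ids])
  if (anyNA(sp)) {
    if (missing_species == "error")
      stop("species_map is missing protein id(s): ",
           paste(utils::head(ids[is.na(sp)], 3), collapse = ", "),
           call. = FALSE)
    sp[is.na(sp)] <- "unknown"
  }
  sp
}

#' @rdname architecture_catalog
#' @param focal_profile the focal domain's profile id.
#' @param coverage_threshold single/long split (default 0.85).
#' @return `copy_number_table()`: data.frame species, single_domain, long.
#' @export
copy_number_table <- function(annotations, focal_profile,
                              species_map = NULL,
                              coverage_threshold = 0.85,
                              missing_species = c("error", "unknown")) {
  missing_species <- match.arg(missing_species)
  rows <- list()
  for (a in annotations) {
    acc <- a$accepted
    foc <- acc[acc$profile_id == focal_profile, , drop = FALSE]
    if (!nrow(foc)) next
    for (i in seq_len(nrow(foc))) {
      cov <- if (!is.null(foc$protein_coverage)) foc$protein_coverage[i]
             else (foc$env_end[i] - foc$env_start[i] + 1) / a$protein_length
      rows[[length(rows) + 1L]] <-
        data.frame(protein_id = a$protein_id,
                   class = classify_coverage(cov, coverage_threshold),
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(species = character(0), single_domain = integer(0),
                      long = integer(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df$species <- species_of(df$protein_id, species_map, missing_species)
  out <- do.call(rbind, lapply(split(df, df$species), function(g)
    data.frame(species = g$species[1],
               single_domain = sum(g$class == "single_domain"),
               long = sum(g$class == "long"), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$species), , drop = FALSE]
}

#' @rdname architecture_catalog
#' @param catalog an [architecture_catalog()] result.
#' @param taxa character vector of species to include as columns (default:
#'   all species seen).
#' @return `presence_absence()`: binary integer matrix, architectures x
#'   species.
#' @export
presence_absence <- function(catalog, taxa = NULL) {
  by_species <- attr(catalog, "by_species")
  taxa <- taxa %||% sort(unique(unlist(by_species)))
  m <- matrix(0L, nrow(catalog), length(taxa),
              dimnames = list(catalog$architecture, taxa))
  for (a in catalog$architecture)
    m[a, intersect(by_species[[a]], taxa)] <- 1L
  m
}

#' @rdname architecture_catalog
#' @param fmap named character vector domain name -> category label.
#' @return `function_summary()`: list with `proportions` (named numeric,
#'   category -> proportion of mapped accepted non-focal domains over all
#'   accepted non-focal domains), `unmapped` count, `total` count.
#' @export
function_summary <- function(annotations, fmap, focal_profile = NULL) {
  doms <- unlist(lapply(annotations, function(a) a$accepted$profile_id))
  if (!is.null(focal_profile)) doms <- doms[doms != focal_profile]
  total <- length(doms)
  if (!total)
    return(list(proportions = setNames(numeric(0), character(0)),
                unmapped = 0L, total = 0L))
  cat <- unname(fmap[doms])
  unmapped <- sum(is.na(cat))
  props <- if (all(is.na(cat))) setNames(numeric(0), character(0)) else
    table(cat[!is.na(cat)]) / total
  list(proportions = setNames(as.numeric(props), names(props)),
       unmapped = unmapped, total = total)
}

#' Default function-category map
#'
#' Small built-in mapping of the partner domains most often fused to the
#' focal domain in the real survey (MCP_signal, HAMP, Cache_1 to signal
#' transduction; response-regulator receivers to phosphorelay response
#' regulation; GGDEF to signal transduction; AMP-binding to catalysis).
#'
#' @return named character vector.
#' @export
default_function_map <- function() {
  c(MCP_signal = "signal transduction", HAMP = "signal transduction",
    Cache_1 = "signal transduction", GGDEF = "signal transduction",
    Response_reg = "phosphorelay response regulation",
    PAS = "signal transduction", SH3 = "protein binding",
    "AMP-binding" = "catalysis")
}
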