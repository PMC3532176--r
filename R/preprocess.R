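#' Filter probes by presence across stage replicates
#'
#' Keeps exactly the probes whose spots are present in at least
#' `min_frac` of the replicates of *every* stage group (the flagging rule
#' "present in at least 80% of the replicates of each experimental
#' condition"). Probe order is preserved.
#'
#' @param x an [expression_matrix()].
#' @param design design table covering all samples of `x` (see
#'   [validate_design()]); the stage groups define the replicate sets.
#' @param min_frac minimum fraction of present replicates per stage,
#'   default 0.8.
#' @return The row-subset `expr_matrix`. Warns when no probe survives.
#' @export
apply_presence_filter <- function(x, design, min_frac = 0.8) {
  stopifnot(inherits(x, "expr_matrix"))
  if (min_frac < 0 || min_frac > 1) stop("min_frac must be in [0, 1]")
  design <- validate_design(design, x)
  keep <- rep(TRUE, nrow(x$intensities))
  for (st in levels(design$stage)) {
    cols <- design$sample[design$stage == st]
    if (!length(cols)) next
    frac <- rowMeans(x$presence[, cols, drop = FALSE])
    keep <- keep & (frac >= min_frac)
  }
  if (!any(keep))
    warning("presence filter removed every probe")
  x[keep, ]
}

#' Median scale normalization across arrays
#'
#' Rescales every array (sample) so its median present intensity equals a
#' common reference, taken as the median of all per-array medians. This is
#' the single-channel "scale-normalized using the median value of each
#' array" step; it preserves the overall intensity scale and is invariant
#' to sample order.
#'
#' @param x an [expression_matrix()]; every sample needs at least one
#'   present spot.
#' @return The normalized `expr_matrix`, with attributes `scale_factors`
#'   (per-sample multipliers) and `reference` (the common median).
#' @export
median_scale_normalize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  n_present <- colSums(x$presence)
  if (any(n_present == 0))
    stop("sample(s) with zero present spots: ",
         paste(colnames(x$intensities)[n_present == 0], collapse = ", "))
  meds <- vapply(seq_len(ncol(x$intensities)), function(j)
    stats::median(x$intensities[x$presence[, j], j]), numeric(1))
  reference <- stats::median(meds)
  factors <- reference / meds
  out <- expression_matrix(sweep(x$intensities, 2, factors, `*`), x$presence)
  attr(out, "scale_factors") <- stats::setNames(factors,
                                                colnames(x$intensities))
  attr(out, "reference") <- reference
  out
}

best_hit_per_query <- function(hits, evalue_max = Inf) {
  # lowest e-value, ties by highest bitscore then lexicographic subject
  hits <- hits[hits$evalue < evalue_max, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  ord <- order(hits$query, hits$evalue, -hits$bitscore, hits$subject)
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(hits$query), , drop = FALSE]
}

#' Map probes to proxy-protein accessions through a two-step homology chain
#'
#' Implements the proxy mapping used when a species has no reference
#' genome: each probe is assigned its best contig hit, each contig its
#' best proxy-protein hit below `evalue_max` (the BlastX rule, e-value
#' < 1e-3), and the composition collapses to the set of unique protein
#' accessions. Best = lowest e-value, ties broken by highest bit score
#' then lexicographic subject id, so the result is deterministic and
#' independent of row order. The same threshold applies to both steps.
#'
#' @param probe_hits data.frame of probe -> contig hits with columns
#'   `query`, `subject`, `evalue`, `bitscore`.
#' @param contig_hits data.frame of contig -> protein hits, same columns.
#' @param evalue_max strict e-value threshold, default 1e-3.
#' @param proxy_species label recorded as the accession namespace.
#' @return A probe -> gene map: data.frame with columns `probe`,
#'   `accession`, `provenance` (`"homology_proxy"`); probes without a
#'   complete sub-threshold chain are recorded in the `unmapped`
#'   attribute, not dropped silently.
#' @export
map_probes_by_homology <- function(probe_hits, contig_hits,
                                   evalue_max = 1e-3,
                                   proxy_species = NA_character_) {
  need <- c("query", "subject", "evalue", "bitscore")
  if (!all(need %in% names(probe_hits)) || !all(need %in% names(contig_hits)))
    stop("hit tables need columns query, subject, evalue, bitscore")
  p2c <- best_hit_per_query(probe_hits, evalue_max)
  c2g <- best_hit_per_query(contig_hits, evalue_max)
  acc <- c2g$subject[match(p2c$subject, c2g$query)]
  ok <- !is.na(acc)
  map <- data.frame(probe = p2c$query[ok], accession = acc[ok],
                    provenance = rep("homology_proxy", sum(ok)),
                    stringsAsFactors = FALSE)
  map <- map[order(map$probe), , drop = FALSE]
  rownames(map) <- NULL
  all_probes <- unique(probe_hits$query)
  attr(map, "unmapped") <- sort(setdiff(all_probes, map$probe))
  attr(map, "proxy_species") <- proxy_species
  map
}

#' Map probes to gene accessions from a platform annotation
#'
#' Direct probe -> accession mapping for platforms with native gene
#' annotation. Probes with an empty accession are dropped (reported in
#' the `unmapped` attribute); duplicate rows repeating the same pair are
#' collapsed; duplicate probes pointing at different accessions violate
#' the one-accession-per-probe invariant and raise an error naming the
#' offenders.
#'
#' @param annotation_table data.frame with columns `probe`, `accession`.
#' @return data.frame with columns `probe`, `accession`, `provenance`
#'   (`"platform_annotation"`).
#' @export
map_probes_direct <- function(annotation_table) {
  if (!all(c("probe", "accession") %in% names(annotation_table)))
    stop("annotation table needs columns 'probe' and 'accession'")
  tab <- data.frame(probe = as.character(annotation_table$probe),
                    accession = as.character(annotation_table$accession),
                    stringsAsFactors = FALSE)
  empty <- is.na(tab$accession) | tab$accession == ""
  unmapped <- unique(tab$probe[empty])
  tab <- unique(tab[!empty, , drop = FALSE])
  dup <- unique(tab$probe[duplicated(tab$probe)])
  if (length(dup))
    stop("probe(s) with conflicting accessions: ",
         paste(dup, collapse = ", "))
  map <- data.frame(probe = tab$probe, accession = tab$accession,
                    provenance = rep("platform_annotation", nrow(tab)),
                    stringsAsFactors = FALSE)
  rownames(map) <- NULL
  attr(map, "unmapped") <- setdiff(unmapped, map$probe)
  map
}

#' Unique accessions of a probe-gene map
#'
#' The downstream orthology unit: many probes may collapse onto one
#' accession, each probe maps to at most one.
#'
#' @param map a probe-gene map from [map_probes_direct()] or
#'   [map_probes_by_homology()].
#' @return sorted character vector of unique accessions.
#' @export
unique_accessions <- function(map) sort(unique(map$accession))
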