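#' Cross-species concordant-expression screen, end to end
#'
#' Runs the whole analysis chain on a multi-species competence-stage
#' study: per species, presence filtering, median scale normalization,
#' one-factor ANOVA with Benjamini-Hochberg correction, per-stage-pair
#' direction calls lifted to gene level; then ortholog-group inference
#' from the similarity table (restricted, as in the original screen, to
#' the differentially expressed genes) — or externally supplied groups —
#' the concordance screen over all species, the subset sweep, and
#' stage-profile clustering of the concordant genes of each species.
#'
#' @param species_data named list (by species); each element a list with
#'   `expr` (an [expression_matrix()]), `design` (design table) and
#'   either `map` (probe-gene map data.frame with `probe`, `accession`)
#'   or `annotation` (probe annotation table passed to
#'   [map_probes_direct()]).
#' @param similarity all-vs-all similarity table (see [as_similarity()]);
#'   ignored when `groups` is given.
#' @param groups optional precomputed ortholog groups (long data.frame,
#'   e.g. from [load_groups()]), bypassing inference.
#' @param min_presence presence-filter threshold (default 0.8).
#' @param alpha ANOVA significance level on adjusted p (default 0.01).
#' @param pair_alpha per-stage-pair significance level (default 0.05).
#' @param evalue_max strict e-value threshold for orthology (default 1e-3).
#' @param inflation MCL inflation (default 1.5).
#' @param require_same_pair concordance witness rule (default TRUE).
#' @param k_clusters clusters for the profile trees (default 3).
#' @return An object of class `ortho_screen`: list with per-species
#'   results (`normalized`, `de`, `directions`, `gene_calls`, `map`),
#'   `groups`, `concordance`, `sweep`, `profiles`, `clustering`, and the
#'   call parameters. See [print.ortho_screen()], [summary.ortho_screen()],
#'   [plot.ortho_screen()].
#' @export
ortho_screen <- function(species_data, similarity = NULL, groups = NULL,
                         min_presence = 0.8, alpha = 0.01,
                         pair_alpha = 0.05, evalue_max = 1e-3,
                         inflation = 1.5, require_same_pair = TRUE,
                         k_clusters = 3) {
  if (is.null(names(species_data)) || length(species_data) < 2)
    stop("species_data must be a named list of >= 2 species")
  per <- list()
  calls <- list()
  for (sp in names(species_data)) {
    sd_ <- species_data[[sp]]
    map <- if (!is.null(sd_$map)) sd_$map else map_probes_direct(sd_$annotation)
    filt <- apply_presence_filter(sd_$expr, sd_$design, min_presence)
    norm <- median_scale_normalize(filt)
    de <- call_de(norm, sd_$design, alpha = alpha)
    dirs <- pairwise_directions(norm, sd_$design, de, pair_alpha = pair_alpha)
    gcalls <- probe_to_gene_directions(dirs, map)
    per[[sp]] <- list(normalized = norm, de = de, directions = dirs,
                      gene_calls = gcalls, map = map, design = sd_$design)
    calls[[sp]] <- gcalls
  }
  if (is.null(groups)) {
    if (is.null(similarity))
      stop("need either 'similarity' or precomputed 'groups'")
    sim <- as_similarity(similarity)
    # OrthoMCL applied to the differentially expressed genes only
    de_keys <- unlist(lapply(names(per), function(sp)
      paste(sp, per[[sp]]$gene_calls$gene, sep = "|")), use.names = FALSE)
    qk <- paste(sim$qspecies, sim$qgene, sep = "|")
    sk <- paste(sim$sspecies, sim$sgene, sep = "|")
    sim <- sim[qk %in% de_keys & sk %in% de_keys, , drop = FALSE]
    groups <- infer_ortholog_groups(sim, species = names(species_data),
                                    evalue_max = evalue_max,
                                    inflation = inflation)
  }
  conc <- if (nrow(groups) &&
              all(names(species_data) %in% unique(groups$species)))
    screen_concordance(groups, calls, names(species_data),
                       require_same_pair) else
    screen_concordance_impl(groups, calls, names(species_data),
                            require_same_pair)
  sweep_tab <- if (nrow(groups)) subset_sweep(groups, calls,
                                              require_same_pair) else NULL
  profiles <- list(); clustering <- list()
  for (sp in names(per)) {
    conc_genes <- unique(unlist(lapply(conc$detail, function(d)
      d$genes[[sp]]), use.names = FALSE))
    if (length(conc_genes) >= 2) {
      pr <- mean_stage_profiles(per[[sp]]$normalized, per[[sp]]$design,
                                ids = conc_genes, map = per[[sp]]$map)
      profiles[[sp]] <- pr
      if (nrow(pr$z) >= 2)
        clustering[[sp]] <- cluster_profiles(pr, k = k_clusters)
    }
  }
  structure(list(species = per, groups = groups, concordance = conc,
                 sweep = sweep_tab, profiles = profiles,
                 clustering = clustering,
                 params = list(min_presence = min_presence, alpha = alpha,
                               pair_alpha = pair_alpha,
                               evalue_max = evalue_max,
                               inflation = inflation,
                               require_same_pair = require_same_pair,
                               k_clusters = k_clusters)),
            class = "ortho_screen")
}

#' @describeIn ortho_screen one-line-per-species overview.
#' @param x,object an `ortho_screen` object.
#' @param ... ignored.
#' @export
print.ortho_screen <- function(x, ...) {
  cat("Cross-species concordant-expression screen\n")
  for (sp in names(x$species)) {
    de <- x$species[[sp]]$de
    cat(sprintf("  %-10s %5d probes tested, %4d DE (q < %.3g), %4d gene-level calls\n",
                sp, sum(is.na(de$reason)), sum(de$significant),
                x$params$alpha, nrow(x$species[[sp]]$gene_calls)))
  }
  cat(sprintf("  ortholog groups: %d; concordant across all %d species: %d\n",
              length(unique(x$groups$group_id)), length(x$species),
              nrow(x$concordance$table)))
  invisible(x)
}

#' @describeIn ortho_screen adds the subset sweep and cluster shapes.
#' @export
summary.ortho_screen <- function(object, ...) {
  print(object)
  if (!is.null(object$sweep)) {
    cat("\nConcordant groups per species subset:\n")
    print(object$sweep[c("subset", "n_species", "n_groups")])
  }
  for (sp in names(object$clustering)) {
    cl <- object$clustering[[sp]]
    cat(sprintf("\n%s profile clusters: %s\n", sp,
                paste(sprintf("%s (n=%d)", rownames(cl$cluster_profiles),
                              tabulate(cl$cluster, cl$k)), collapse = ", ")))
  }
  invisible(object)
}

#' @describeIn ortho_screen mean standardized stage profile of every
#'   cluster, one panel per species.
#' @export
plot.ortho_screen <- function(x, ...) {
  cls <- x$clustering
  if (!length(cls)) {
    warning("nothing to plot: no concordant profiles")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(1, length(cls)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (sp in names(cls)) {
    m <- cls[[sp]]$cluster_profiles
    graphics::matplot(t(m), type = "b", pch = 19, lty = 1, xaxt = "n",
                      xlab = "stage", ylab = "mean standardized log2",
                      main = sp, ...)
    graphics::axis(1, at = 1:3, labels = STAGES)
    graphics::legend("topleft", legend = rownames(m), col = seq_len(nrow(m)),
                     lty = 1, pch = 19, bty = "n", cex = 0.8)
  }
  invisible(x)
}
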