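#' Screen ortholog groups for cross-species concordant regulation
#'
#' The core cross-species screen: an ortholog group qualifies when there
#' is at least one (stage pair, sign) witness such that every species in
#' `species_subset` contributes at least one member gene carrying that
#' exact direction call (`require_same_pair = TRUE`, the strict reading
#' of "similar differential expression between at least 2 of the 3
#' stages"). With `require_same_pair = FALSE` each species only needs
#' some call of the matching sign on any stage pair. All qualifying
#' witnesses are reported, together with the witnessing member genes and
#' their counts per species.
#'
#' @param groups ortholog groups: data.frame with columns `group_id`,
#'   `species`, `gene` (as from [mcl()] or [load_groups()]).
#' @param calls_by_species named list (by species) of gene-level
#'   direction calls from [probe_to_gene_directions()].
#' @param species_subset species that must all witness the regulation
#'   (default: all species in `calls_by_species`); at least 2.
#' @param require_same_pair require the witness on the same stage pair
#'   in every species (default TRUE).
#' @return An object of class `concordance`: list with `table` (one row
#'   per concordant group: `group_id`, `n_witnesses`, `witnesses` as a
#'   `pair:sign` string, and `genes_<species>` counts), `detail` (per
#'   group: witness data.frame and witnessing genes per species),
#'   `species_subset`, `require_same_pair`.
#' @export
screen_concordance <- function(groups, calls_by_species,
                               species_subset = names(calls_by_species),
                               require_same_pair = TRUE) {
  if (length(species_subset) < 2)
    stop("species_subset needs >= 2 species")
  if (!all(species_subset %in% names(calls_by_species)))
    stop("no direction calls for: ",
         paste(setdiff(species_subset, names(calls_by_species)),
               collapse = ", "))
  absent <- setdiff(species_subset, unique(groups$species))
  if (length(absent))
    stop("species absent from every group: ", paste(absent, collapse = ", "))
  screen_concordance_impl(groups, calls_by_species, species_subset,
                          require_same_pair)
}

screen_concordance_impl <- function(groups, calls_by_species, species_subset,
                                    require_same_pair) {
  # per species: gene -> its set of (pair, sign) calls
  call_key <- lapply(calls_by_species[species_subset], function(cl) {
    if (!nrow(cl)) return(cl)
    unique(cl[c("gene", "pair", "sign")])
  })
  detail <- list()
  rows <- list()
  for (gid in unique(groups$group_id)) {
    mem <- groups[groups$group_id == gid, , drop = FALSE]
    per_sp <- lapply(species_subset, function(sp) {
      genes <- mem$gene[mem$species == sp]
      cl <- call_key[[sp]]
      if (!length(genes) || !nrow(cl)) return(cl[0, , drop = FALSE])
      cl[cl$gene %in% genes, , drop = FALSE]
    })
    names(per_sp) <- species_subset
    if (any(vapply(per_sp, nrow, integer(1)) == 0)) next
    if (require_same_pair) {
      wit <- unique(per_sp[[1]][c("pair", "sign")])
      for (sp in species_subset[-1]) {
        other <- unique(per_sp[[sp]][c("pair", "sign")])
        wit <- merge(wit, other, by = c("pair", "sign"))
      }
      if (!nrow(wit)) next
      wit <- wit[order(wit$pair, wit$sign), , drop = FALSE]
      genes <- lapply(per_sp, function(cl) {
        hit <- merge(cl, wit, by = c("pair", "sign"))
        sort(unique(hit$gene))
      })
    } else {
      signs <- Reduce(intersect, lapply(per_sp, function(cl) unique(cl$sign)))
      if (!length(signs)) next
      wit <- data.frame(pair = NA_character_, sign = sort(signs),
                        stringsAsFactors = FALSE)
      genes <- lapply(per_sp, function(cl)
        sort(unique(cl$gene[cl$sign %in% signs])))
    }
    rownames(wit) <- NULL
    detail[[gid]] <- list(witnesses = wit, genes = genes)
    counts <- vapply(genes, length, integer(1))
    row <- data.frame(group_id = gid, n_witnesses = nrow(wit),
                      witnesses = paste(paste0(ifelse(is.na(wit$pair), "any",
                                                      wit$pair),
                                               ":",
                                               ifelse(wit$sign > 0, "+", "-")),
                                        collapse = ","),
                      stringsAsFactors = FALSE)
    for (sp in species_subset) row[[paste0("genes_", sp)]] <- counts[[sp]]
    rows[[length(rows) + 1L]] <- row
  }
  tab <- if (length(rows)) do.call(rbind, rows) else {
    tab0 <- data.frame(group_id = character(), n_witnesses = integer(),
                       witnesses = character(), stringsAsFactors = FALSE)
    for (sp in species_subset) tab0[[paste0("genes_", sp)]] <- integer()
    tab0
  }
  rownames(tab) <- NULL
  structure(list(table = tab, detail = detail,
                 species_subset = species_subset,
                 require_same_pair = require_same_pair),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("concordance screen: %d group(s) concordant across {%s}%s\n",
              nrow(x$table), paste(x$species_subset, collapse = ", "),
              if (x$require_same_pair) " (same stage pair)" else
                " (any stage pair)"))
  if (nrow(x$table)) print(utils::head(x$table, 10))
  invisible(x)
}

#' Concordance counts over every species subset
#'
#' Runs [screen_concordance()] for every subset of at least two species
#' and tabulates the number of concordant groups and witnessing member
#' genes per species — the table behind the "in at least 2 / 3 / 4
#' species" nesting of the screen. A species absent from every group
#' simply contributes zero counts here (the interactive screen would
#' error).
#'
#' @param groups ortholog groups (long data.frame).
#' @param calls_by_species named list of gene-level direction calls.
#' @param require_same_pair as in [screen_concordance()].
#' @return data.frame with one row per subset: `subset`, `n_species`,
#'   `n_groups`, and `genes_<species>` counts (NA for species outside
#'   the subset). The per-subset concordant group ids are in the
#'   `group_ids` attribute (named list).
#' @export
subset_sweep <- function(groups, calls_by_species, require_same_pair = TRUE) {
  species <- names(calls_by_species)
  if (length(species) < 2) stop("need >= 2 species")
  rows <- list(); gids <- list()
  for (k in 2:length(species)) {
    cmb <- utils::combn(species, k)
    for (j in seq_len(ncol(cmb))) {
      sub <- cmb[, j]
      sc <- screen_concordance_impl(groups, calls_by_species, sub,
                                    require_same_pair)
      lab <- paste(sub, collapse = "+")
      row <- data.frame(subset = lab, n_species = k,
                        n_groups = nrow(sc$table), stringsAsFactors = FALSE)
      for (sp in species)
        row[[paste0("genes_", sp)]] <- if (sp %in% sub)
          sum(sc$table[[paste0("genes_", sp)]]) else NA_integer_
      rows[[length(rows) + 1L]] <- row
      gids[[lab]] <- sc$table$group_id
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "group_ids") <- gids
  out
}

#' Mean per-stage expression profiles
#'
#' For each probe (or, through a probe-gene map, each gene) computes the
#' mean log2 present intensity at NC1, C1 and C2, plus a standardized
#' copy (zero mean, unit variance across the three stages; all-equal
#' profiles standardize to zeros) used for clustering. Entities with an
#' empty stage are dropped and reported in the `dropped` attribute.
#'
#' @param x an [expression_matrix()].
#' @param design design table for `x`.
#' @param ids optional subset of entity ids to keep.
#' @param map optional probe-gene map; when given, profiles are computed
#'   per gene over all spots of its probes.
#' @return An object of class `stage_profiles`: list with `mean` and `z`
#'   (matrices, rows = entities, columns NC1, C1, C2).
#' @export
mean_stage_profiles <- function(x, design, ids = NULL, map = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  design <- validate_design(design, x)
  logm <- log2_present(x)
  entity <- rownames(logm)
  if (!is.null(map)) {
    idx <- match(rownames(logm), map$probe)
    entity <- map$accession[idx]
    keep <- !is.na(entity)
    logm <- logm[keep, , drop = FALSE]
    entity <- entity[keep]
  }
  if (!is.null(ids)) {
    keep <- entity %in% ids
    logm <- logm[keep, , drop = FALSE]
    entity <- entity[keep]
  }
  ents <- unique(entity)
  prof <- matrix(NA_real_, length(ents), 3,
                 dimnames = list(ents, STAGES))
  for (st in STAGES) {
    cols <- which(design$stage == st)
    sub <- logm[, cols, drop = FALSE]
    for (e in ents) {
      v <- sub[entity == e, , drop = FALSE]
      v <- v[!is.na(v)]
      if (length(v)) prof[e, st] <- mean(v)
    }
  }
  dropped <- ents[rowSums(is.na(prof)) > 0]
  if (length(dropped)) {
    warning(length(dropped), " profile(s) dropped (empty stage group)")
    prof <- prof[setdiff(ents, dropped), , drop = FALSE]
  }
  # population standardization: the three stage means are the whole
  # profile, not a sample from it
  z <- t(apply(prof, 1, function(v) {
    s <- sqrt(mean((v - mean(v))^2))
    if (s == 0) rep(0, 3) else (v - mean(v)) / s
  }))
  colnames(z) <- STAGES
  structure(list(mean = prof, z = z), class = "stage_profiles",
            dropped = dropped)
}

#' @export
print.stage_profiles <- function(x, ...) {
  cat(sprintf("stage_profiles: %d entities x 3 stages (NC1, C1, C2)\n",
              nrow(x$mean)))
  invisible(x)
}

# Centred-Pearson distance matrix of standardized 3-stage profiles.
# The z rows are centred with sum of squares 3 (population sd), so the
# Pearson correlation is tcrossprod(z) / 3; flat (all-zero) profiles get
# correlation 0, i.e. distance 1, to everything.
profile_distance <- function(z) {
  C <- tcrossprod(z) / 3
  C[!is.finite(C)] <- 0
  C <- pmin(pmax(C, -1), 1)
  D <- 1 - C
  diag(D) <- 0
  D
}

#' Hierarchical clustering of stage profiles
#'
#' Average-linkage agglomerative clustering under the distance
#' 1 - centred Pearson correlation (the CLUSTER/TREEVIEW pairing), with
#' the tree cut into `k` clusters. Clusters are labelled by the nearest
#' ideal shape of their mean standardized profile, by centred
#' correlation: `up_at_C2` (monotone rise peaking at C2), `down_at_C2`
#' (fall to a C2 minimum), or `peak_at_C1` (the transient class
#' up-regulated at C1 and down again at C2). Nearest-shape matching is
#' used instead of argmax/argmin rules because two stages of an ideal
#' shape can coincide in expectation (NC1 and C1 for `down_at_C2`, NC1
#' and C2 for `peak_at_C1`), which would let pure noise decide the
#' label. A cluster correlating with no shape is labelled `other`. When every profile is
#' flat the result is a single degenerate cluster labelled `flat`.
#'
#' @param profiles a `stage_profiles` from [mean_stage_profiles()].
#' @param k number of clusters to cut (default 3: the two major classes
#'   plus the minor transient one).
#' @return list with `hclust` (the tree, NULL in the degenerate case),
#'   `cluster` (integer cluster index per entity), `labels` (shape label
#'   per entity), `cluster_profiles` (mean z profile per cluster), `k`.
#' @export
cluster_profiles <- function(profiles, k = 3) {
  stopifnot(inherits(profiles, "stage_profiles"))
  z <- profiles$z
  if (nrow(z) < 2) stop("need >= 2 profiles")
  if (all(z == 0)) {
    return(list(hclust = NULL,
                cluster = stats::setNames(rep(1L, nrow(z)), rownames(z)),
                labels = stats::setNames(rep("flat", nrow(z)), rownames(z)),
                cluster_profiles = matrix(0, 1, 3,
                                          dimnames = list("1", STAGES)),
                k = 1L))
  }
  k <- min(k, nrow(z))
  D <- profile_distance(z)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  cl <- stats::cutree(hc, k = k)
  means <- t(vapply(seq_len(k), function(i)
    colMeans(z[cl == i, , drop = FALSE]), numeric(3)))
  colnames(means) <- STAGES
  shapes <- rbind(up_at_C2   = c(-1, -1, 2),
                  down_at_C2 = c(1, 1, -2),
                  peak_at_C1 = c(-1, 2, -1))
  shapes <- shapes / sqrt(rowSums(shapes^2))
  lab <- vapply(seq_len(k), function(i) {
    m <- means[i, ] - mean(means[i, ])
    nm <- sqrt(sum(m^2))
    if (nm == 0) return("flat")
    r <- as.vector(shapes %*% (m / nm))
    if (max(r) <= 0) return("other")
    rownames(shapes)[which.max(r)]
  }, character(1))
  # disambiguate repeated shape labels deterministically
  lab <- stats::ave(lab, lab, FUN = function(v)
    if (length(v) == 1) v else paste0(v, "_", seq_along(v)))
  rownames(means) <- lab
  list(hclust = hc, cluster = cl,
       labels = stats::setNames(lab[cl], names(cl)),
       cluster_profiles = means, k = k)
}
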