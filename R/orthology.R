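#' Reciprocal best hits between two species
#'
#' From an all-vs-all similarity table, finds the gene pairs (a, b) such
#' that b is a's best sub-threshold hit in species B and a is b's best
#' sub-threshold hit in species A. Best = lowest e-value, ties broken by
#' highest bit score then lexicographic subject id, so the result does
#' not depend on record order. Self-hits and within-species hits are
#' ignored.
#'
#' @param records similarity table (see [as_similarity()]).
#' @param species_a,species_b the two species labels.
#' @param evalue_max strict e-value threshold (default 1e-3).
#' @return data.frame with columns `species_a`, `gene_a`, `species_b`,
#'   `gene_b`, `evalue_ab`, `evalue_ba` (one row per reciprocal pair;
#'   possibly empty).
#' @export
rbh_pairs <- function(records, species_a, species_b, evalue_max = 1e-3) {
  records <- as_similarity(records)
  best_dir <- function(sp_q, sp_s) {
    h <- records[records$qspecies == sp_q & records$sspecies == sp_s &
                   records$qgene != records$sgene &
                   records$evalue < evalue_max, , drop = FALSE]
    if (!nrow(h)) return(h)
    ord <- order(h$qgene, h$evalue, -h$bitscore, h$sgene)
    h <- h[ord, , drop = FALSE]
    h[!duplicated(h$qgene), , drop = FALSE]
  }
  ab <- best_dir(species_a, species_b)
  ba <- best_dir(species_b, species_a)
  if (!nrow(ab) || !nrow(ba))
    return(data.frame(species_a = character(), gene_a = character(),
                      species_b = character(), gene_b = character(),
                      evalue_ab = numeric(), evalue_ba = numeric(),
                      stringsAsFactors = FALSE))
  key_ab <- paste(ab$qgene, ab$sgene, sep = "\r")
  key_ba <- paste(ba$sgene, ba$qgene, sep = "\r")
  hit <- match(key_ab, key_ba)
  keep <- !is.na(hit)
  out <- data.frame(species_a = rep(species_a, sum(keep)),
                    gene_a = ab$qgene[keep],
                    species_b = rep(species_b, sum(keep)),
                    gene_b = ab$sgene[keep],
                    evalue_ab = ab$evalue[keep],
                    evalue_ba = ba$evalue[hit[keep]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Within-species in-paralog pairs
#'
#' A within-species pair (a, a') is an in-paralog edge when its mutual
#' e-value beats (is smaller than) the best cross-species hit e-value of
#' *both* genes, and at least one of the two has a cross-species ortholog
#' (the anchoring clause that attaches recent duplicates to groups). The
#' mutual e-value is taken as the worst of the directed e-values present
#' (OrthoMCL averages; the maximum is the conservative choice). Genes
#' with no cross-species hit at all contribute `Inf` as their best
#' cross-species e-value, but a species with no orthologs anywhere yields
#' no edges because nothing is anchored.
#'
#' @param records similarity table (see [as_similarity()]).
#' @param species species label.
#' @param ortholog_genes character vector of this species' genes that
#'   appear in some reciprocal-best-hit pair.
#' @return data.frame with columns `species`, `gene_a`, `gene_b`
#'   (`gene_a < gene_b`), `evalue_ab`, `evalue_ba`, `mutual_evalue`.
#' @export
find_inparalogs <- function(records, species, ortholog_genes) {
  records <- as_similarity(records)
  empty <- data.frame(species = character(), gene_a = character(),
                      gene_b = character(), evalue_ab = numeric(),
                      evalue_ba = numeric(), mutual_evalue = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(ortholog_genes)) return(empty)
  cross <- records[records$qspecies == species &
                     records$sspecies != species, , drop = FALSE]
  best_cross <- tapply(cross$evalue, cross$qgene, min)
  bc <- function(g) {
    v <- best_cross[g]
    ifelse(is.na(v), Inf, v)
  }
  within <- records[records$qspecies == species &
                      records$sspecies == species &
                      records$qgene != records$sgene, , drop = FALSE]
  if (!nrow(within)) return(empty)
  a <- pmin(within$qgene, within$sgene)
  b <- pmax(within$qgene, within$sgene)
  key <- paste(a, b, sep = "\r")
  keys <- sort(unique(key))
  dir_lab <- ifelse(within$qgene == a, "ab", "ba")
  min_by <- function(x) {
    v <- tapply(x, factor(key, keys),
                function(v) if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
    as.numeric(v)
  }
  # best e-value per direction of each unordered pair
  e_ab <- min_by(ifelse(dir_lab == "ab", within$evalue, NA_real_))
  e_ba <- min_by(ifelse(dir_lab == "ba", within$evalue, NA_real_))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  ga <- vapply(parts, `[`, character(1), 1)
  gb <- vapply(parts, `[`, character(1), 2)
  mutual <- pmax(e_ab, e_ba, na.rm = TRUE)
  keep <- mutual < pmin(bc(ga), bc(gb)) &
    (ga %in% ortholog_genes | gb %in% ortholog_genes)
  out <- data.frame(species = rep(species, sum(keep)),
                    gene_a = ga[keep], gene_b = gb[keep],
                    evalue_ab = e_ab[keep], evalue_ba = e_ba[keep],
                    mutual_evalue = mutual[keep], stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# -log10 e-value with the OrthoMCL cap: e = 0 (or < 1e-300) maps to 300;
# negative raw weights (e > 1) are clamped to 0.
neglog10_capped <- function(e) {
  w <- ifelse(e <= 1e-300, 300, -log10(e))
  pmin(pmax(w, 0), 300)
}

#' Build the normalized ortholog similarity graph
#'
#' Combines reciprocal-best-hit edges and in-paralog edges into one
#' weighted undirected graph. Raw edge weight is the mean of
#' `-log10(e-value)` over the available directions, with e-value 0 capped
#' at weight 300. Weights are then normalized by the mean raw weight of
#' their category class — ortholog edges per species pair, in-paralog
#' edges per species — the OrthoMCL device that stops fast-evolving or
#' close species pairs from dominating the clustering.
#'
#' @param rbh data.frame from [rbh_pairs()] (possibly several species
#'   pairs row-bound together).
#' @param inparalogs data.frame from [find_inparalogs()] (possibly
#'   several species row-bound), or NULL.
#' @return An object of class `ortho_graph`: data.frame with columns
#'   `node_a`, `node_b` (`species|gene` keys), `weight` (normalized),
#'   `raw_weight`, `category` (`ortholog`/`inparalog`), `class_key`.
#' @export
build_graph <- function(rbh, inparalogs = NULL) {
  pieces <- list()
  if (!is.null(rbh) && nrow(rbh)) {
    raw <- rowMeans(cbind(neglog10_capped(rbh$evalue_ab),
                          neglog10_capped(rbh$evalue_ba)))
    sp_key <- apply(cbind(rbh$species_a, rbh$species_b), 1,
                    function(v) paste(sort(v), collapse = ":"))
    pieces$ortholog <- data.frame(
      node_a = paste(rbh$species_a, rbh$gene_a, sep = "|"),
      node_b = paste(rbh$species_b, rbh$gene_b, sep = "|"),
      raw_weight = raw, category = "ortholog", class_key = sp_key,
      stringsAsFactors = FALSE)
  }
  if (!is.null(inparalogs) && nrow(inparalogs)) {
    wa <- neglog10_capped(inparalogs$evalue_ab)
    wb <- neglog10_capped(inparalogs$evalue_ba)
    raw <- rowMeans(cbind(wa, wb), na.rm = TRUE)
    pieces$inparalog <- data.frame(
      node_a = paste(inparalogs$species, inparalogs$gene_a, sep = "|"),
      node_b = paste(inparalogs$species, inparalogs$gene_b, sep = "|"),
      raw_weight = raw, category = "inparalog",
      class_key = inparalogs$species, stringsAsFactors = FALSE)
  }
  if (!length(pieces)) {
    g <- data.frame(node_a = character(), node_b = character(),
                    weight = numeric(), raw_weight = numeric(),
                    category = character(), class_key = character(),
                    stringsAsFactors = FALSE)
    return(structure(g, class = c("ortho_graph", "data.frame")))
  }
  g <- do.call(rbind, pieces)
  rownames(g) <- NULL
  key <- paste(g$category, g$class_key)
  class_mean <- tapply(g$raw_weight, key, mean)
  g$weight <- g$raw_weight / as.numeric(class_mean[key])
  g$weight[!is.finite(g$weight)] <- 0   # class mean 0: degenerate, drop weight
  g <- g[c("node_a", "node_b", "weight", "raw_weight", "category",
           "class_key")]
  structure(g, class = c("ortho_graph", "data.frame"))
}

#' Markov clustering of the ortholog graph
#'
#' MCL on the column-stochastic transition matrix with identity
#' self-loops: alternate expansion (matrix squaring), inflation
#' (entrywise power followed by column renormalization) and pruning
#' (entries below `prune_below` zeroed, columns renormalized) until the
#' largest entry change falls under `tol` or `max_iter` is reached. The
#' graph is first split into connected components, which MCL can never
#' merge, so large collections of singletons cost nothing. Clusters are
#' read off the attractor structure: rows with positive diagonal mass
#' claim their positive columns; attractors claiming each other form one
#' attractor system; a node claimed by several systems goes to the one
#' holding more of its column mass, ties broken lexicographically. Every
#' node ends up in exactly one group.
#'
#' @param graph an `ortho_graph` from [build_graph()] (or any data.frame
#'   with `node_a`, `node_b`, `weight`).
#' @param inflation inflation exponent (granularity; default 1.5, the
#'   OrthoMCL default).
#' @param max_iter iteration cap; non-convergence returns the current
#'   clustering with a warning and `converged = FALSE` attribute.
#' @param prune_below pruning threshold for small matrix entries.
#' @param tol convergence tolerance on the max entry change.
#' @return data.frame with columns `group_id`, `species`, `gene` (one row
#'   per member); groups are named `OG_%04d` in decreasing size order.
#'   Attribute `converged` reports per-component convergence overall.
#' @export
mcl <- function(graph, inflation = 1.5, max_iter = 100L, prune_below = 1e-5,
                tol = 1e-6) {
  if (!nrow(graph)) stop("empty graph")
  if (inflation <= 1) stop("inflation must exceed 1")
  ig <- igraph::graph_from_data_frame(
    graph[c("node_a", "node_b", "weight")], directed = FALSE)
  comp <- igraph::components(ig)
  membership <- comp$membership
  clusters <- list()
  converged <- TRUE
  for (ci in seq_len(comp$no)) {
    nodes <- sort(names(membership)[membership == ci])
    if (length(nodes) == 1L) {
      clusters[[length(clusters) + 1L]] <- nodes
      next
    }
    sel <- graph$node_a %in% nodes
    A <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    ea <- graph$node_a[sel]; eb <- graph$node_b[sel]; w <- graph$weight[sel]
    A[cbind(ea, eb)] <- w
    A[cbind(eb, ea)] <- w
    diag(A) <- diag(A) + 1   # identity self-loops
    res <- mcl_component(A, inflation, max_iter, prune_below, tol)
    converged <- converged && res$converged
    clusters <- c(clusters, res$clusters)
  }
  if (!converged)
    warning("MCL did not converge within max_iter on some component(s)")
  sizes <- lengths(clusters)
  first <- vapply(clusters, `[`, character(1), 1)
  ord <- order(-sizes, first)
  clusters <- clusters[ord]
  gid <- sprintf("OG_%04d", seq_along(clusters))
  nodes <- unlist(clusters, use.names = FALSE)
  parts <- split_taxon_id(nodes)
  out <- data.frame(group_id = rep(gid, lengths(clusters)),
                    species = parts$species, gene = parts$gene,
                    stringsAsFactors = FALSE)
  attr(out, "converged") <- converged
  out
}

# MCL iteration on one dense component; returns clusters as sorted
# character vectors of node names.
mcl_component <- function(A, inflation, max_iter, prune_below, tol) {
  normalize_cols <- function(M) {
    cs <- colSums(M)
    cs[cs == 0] <- 1
    sweep(M, 2, cs, `/`)
  }
  M <- normalize_cols(A)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                      # expansion
    M2 <- normalize_cols(M2^inflation) # inflation
    M2[M2 < prune_below] <- 0          # pruning
    M2 <- normalize_cols(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  nodes <- rownames(M)
  attractors <- nodes[diag(M) > sqrt(.Machine$double.eps)]
  if (!length(attractors))
    return(list(clusters = list(sort(nodes)), converged = converged))
  # attractor systems: attractors supporting mass on each other merge
  k <- length(attractors)
  sysid <- seq_len(k)
  Msub <- M[attractors, attractors, drop = FALSE]
  link <- (Msub > 0) | (t(Msub) > 0)
  repeat {
    changed <- FALSE
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (link[i, j] && sysid[j] != sysid[i]) {
        sysid[sysid == sysid[j]] <- sysid[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  assign <- character(length(nodes))
  names(assign) <- nodes
  for (j in seq_along(nodes)) {
    mass <- M[attractors, j]
    if (all(mass == 0)) {              # orphan: keep as its own singleton
      assign[j] <- paste0("orphan:", nodes[j])
      next
    }
    top <- which(mass == max(mass))
    best <- attractors[top][order(attractors[top])][1]
    assign[j] <- as.character(sysid[match(best, attractors)])
  }
  list(clusters = unname(lapply(split(nodes, assign), sort)),
       converged = converged)
}

#' Read ortholog groups in the OrthoMCL groups.txt dialect
#'
#' Lines have the form `GROUPID: species|gene species|gene ...`. Genes
#' repeated inside one group are deduplicated silently; a gene appearing
#' in two different groups violates the partition invariant and raises
#' an error, as does a malformed line (reported with its line number).
#'
#' @param path file path (or a character vector of lines via `text`).
#' @param text optional character vector of lines, bypassing `path`.
#' @return data.frame with columns `group_id`, `species`, `gene`.
#' @examples
#' load_groups(text = "OG_10201: mmu|Tnfrsf23 bta|TNFRSF23")
#' @export
load_groups <- function(path, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path)
  keep <- nzchar(trimws(lines))
  out <- list()
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    ln <- trimws(lines[i])
    m <- regmatches(ln, regexec("^(\\S+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3 || !nzchar(m[2]))
      stop("malformed group line ", i, ": ", ln)
    gid <- m[2]
    toks <- strsplit(trimws(m[3]), "\\s+")[[1]]
    toks <- unique(toks[nzchar(toks)])
    if (!length(toks))
      stop("malformed group line ", i, " (no members): ", ln)
    parts <- split_taxon_id(toks)
    out[[length(out) + 1L]] <- data.frame(group_id = gid,
                                          species = parts$species,
                                          gene = parts$gene,
                                          stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(group_id = character(), species = character(),
                      gene = character(), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  per_group <- unique(df[c("group_id", "species", "gene")])
  k2 <- paste(per_group$species, per_group$gene, sep = "|")
  clash <- unique(k2[duplicated(k2)])
  if (length(clash))
    stop("gene(s) in more than one group: ", paste(clash, collapse = ", "))
  rownames(df) <- NULL
  df
}

#' Write ortholog groups in the OrthoMCL groups.txt dialect
#'
#' @param groups data.frame with columns `group_id`, `species`, `gene`.
#' @param path output file.
#' @export
write_groups <- function(groups, path) {
  sp <- split(paste(groups$species, groups$gene, sep = "|"), groups$group_id)
  lines <- vapply(names(sp), function(g)
    paste0(g, ": ", paste(sp[[g]], collapse = " ")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Infer ortholog groups from a similarity table
#'
#' Convenience wrapper chaining the OrthoMCL-style stages: reciprocal
#' best hits for every species pair, in-paralog detection per species,
#' graph construction with per-class weight normalization, and Markov
#' clustering.
#'
#' @param records similarity table (see [as_similarity()]).
#' @param species species to include (default: all in `records`).
#' @param evalue_max strict e-value threshold for RBH (default 1e-3).
#' @param inflation MCL inflation (default 1.5).
#' @param ... further arguments passed to [mcl()].
#' @return groups data.frame as from [mcl()], or an empty groups frame
#'   when no edge survives.
#' @export
infer_ortholog_groups <- function(records, species = NULL, evalue_max = 1e-3,
                                  inflation = 1.5, ...) {
  records <- as_similarity(records)
  if (is.null(species))
    species <- sort(unique(c(records$qspecies, records$sspecies)))
  rbh_all <- list()
  if (length(species) >= 2) {
    cmb <- utils::combn(species, 2)
    for (k in seq_len(ncol(cmb)))
      rbh_all[[k]] <- rbh_pairs(records, cmb[1, k], cmb[2, k], evalue_max)
  }
  rbh <- if (length(rbh_all)) do.call(rbind, rbh_all) else NULL
  inp <- NULL
  if (!is.null(rbh) && nrow(rbh)) {
    inp_all <- lapply(species, function(sp) {
      anchored <- c(rbh$gene_a[rbh$species_a == sp],
                    rbh$gene_b[rbh$species_b == sp])
      find_inparalogs(records, sp, unique(anchored))
    })
    inp <- do.call(rbind, inp_all)
  }
  g <- build_graph(rbh, inp)
  if (!nrow(g))
    return(data.frame(group_id = character(), species = character(),
                      gene = character(), stringsAsFactors = FALSE))
  mcl(g, inflation = inflation, ...)
}
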