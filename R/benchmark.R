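#' Match recovered groups to planted groups by member overlap
#'
#' Two groups match when the Jaccard index of their `species|gene` member
#' sets exceeds 0.5, so a recovered group missing (or adding) a minority
#' of members still counts while merged or shattered groups do not.
#'
#' @param found list of character vectors of `species|gene` members.
#' @param truth list of character vectors of `species|gene` members.
#' @return list with `precision` (fraction of `found` matching some
#'   planted group) and `recall` (fraction of `truth` matched).
#' @export
match_planted_groups <- function(found, truth) {
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  matched_t <- vapply(truth, function(t)
    any(vapply(found, function(f) jac(f, t) > 0.5, logical(1))), logical(1))
  matched_f <- vapply(found, function(f)
    any(vapply(truth, function(t) jac(f, t) > 0.5, logical(1))), logical(1))
  list(precision = if (length(found)) mean(matched_f) else NA_real_,
       recall = if (length(truth)) mean(matched_t) else NA_real_)
}

truth_member_sets <- function(truth) {
  lapply(truth$group_membership, function(m)
    sort(paste(m$species, m$gene, sep = "|")))
}

concordant_member_sets <- function(conc) {
  lapply(conc$detail, function(d)
    sort(unlist(lapply(names(d$genes), function(sp)
      paste(sp, d$genes[[sp]], sep = "|")), use.names = FALSE)))
}

#' Null-calibration study of the full pipeline
#'
#' Simulates a four-species study with no stage effects anywhere
#' (`effect_size = 0`) and measures what the pipeline finds: the
#' per-species fraction of probes declared differentially expressed at
#' adjusted p < 0.01, the number of all-species concordant groups, and
#' the fraction of annotation terms called enriched at q < 0.05 for a
#' planted-size gene list against a null annotation. Under correct FDR
#' control all three stay at (or below) their nominal levels.
#'
#' @param seed integer seed.
#' @param n_probes probes per species (default 5000).
#' @return list with `de_fraction` (named per species), `max_de_fraction`,
#'   `de_se` (binomial standard error at the nominal level),
#'   `n_concordant`, `enrichment_fp_rate`, `n_terms`, and `config`.
#' @export
benchmark_null <- function(seed, n_probes = 5000) {
  cfg <- sim_config(n_probes_per_species = n_probes, effect_size = 0,
                    n_terms = 100, seed = seed)
  sim <- simulate_experiment(cfg)
  rec <- simulate_similarity(sim$truth, cfg)
  res <- ortho_screen(lapply(sim$species, function(s)
    list(expr = s$expr, design = s$design, annotation = s$annotation)),
    similarity = rec)
  de_fraction <- vapply(res$species, function(s) {
    de <- s$de
    tested <- sum(is.na(de$reason))
    sum(de$significant) / tested
  }, numeric(1))
  # null annotation: no preferential sampling anywhere
  ann <- simulate_annotation(sim$truth, cfg, p_planted = 0.05,
                             p_background = 0.05)
  sp1 <- cfg$species_names[1]
  lst <- unlist(lapply(sim$truth$group_membership, function(m)
    m$gene[m$species == sp1]), use.names = FALSE)
  bg <- sim$species[[sp1]]$annotation$accession
  er <- enrich(lst, bg, ann)
  list(de_fraction = de_fraction,
       max_de_fraction = max(de_fraction),
       de_se = sqrt(0.01 * 0.99 / n_probes),
       n_concordant = nrow(res$concordance$table),
       enrichment_fp_rate = if (nrow(er)) mean(er$significant) else 0,
       n_terms = nrow(er),
       config = cfg)
}

#' Planted-recovery study of the full pipeline
#'
#' Simulates the default benchmark — 50 planted four-species ortholog
#' groups with two-fold stage effects, log2 noise s.d. 0.35 and 6/14/8
#' replicates — runs the whole chain, and scores it against the planted
#' truth: precision and recall of the concordance screen (member-set
#' Jaccard matching), adjusted Rand index of the inferred ortholog
#' partition over planted genes, the fraction of planted genes whose
#' profile cluster matches their planted class, the worst adjusted
#' p-value of the planted enriched terms, and the subset-sweep nesting
#' checks (counts non-increasing with subset size; the all-species group
#' set contained in every three-species set).
#'
#' @param seed integer seed.
#' @param n_groups planted groups (default 50).
#' @param n_probes probes per species (default 2000).
#' @return list of scores; see Details in the source.
#' @export
benchmark_planted <- function(seed, n_groups = 50, n_probes = 2000) {
  cfg <- sim_config(n_probes_per_species = n_probes,
                    n_planted_groups = n_groups, seed = seed)
  sim <- simulate_experiment(cfg)
  rec <- simulate_similarity(sim$truth, cfg)
  res <- ortho_screen(lapply(sim$species, function(s)
    list(expr = s$expr, design = s$design, annotation = s$annotation)),
    similarity = rec)

  truth_sets <- truth_member_sets(sim$truth)
  found_sets <- concordant_member_sets(res$concordance)
  pr <- match_planted_groups(found_sets, truth_sets)

  # orthology module scored on the full similarity table
  groups_full <- infer_ortholog_groups(rec)
  truth_lab <- unlist(lapply(names(sim$truth$group_membership), function(g) {
    m <- sim$truth$group_membership[[g]]
    stats::setNames(rep(g, nrow(m)), paste(m$species, m$gene, sep = "|"))
  }))
  got_lab <- stats::setNames(groups_full$group_id,
                             paste(groups_full$species, groups_full$gene,
                                   sep = "|"))
  if (!requireNamespace("mclust", quietly = TRUE))
    stop("the 'mclust' package is required for the adjusted Rand index")
  ari <- mclust::adjustedRandIndex(truth_lab[names(truth_lab)],
                                   got_lab[names(truth_lab)])

  # profile-class recovery for the first species' planted genes
  sp1 <- cfg$species_names[1]
  planted1 <- unlist(lapply(sim$truth$group_membership, function(m)
    m$gene[m$species == sp1]), use.names = FALSE)
  s1 <- res$species[[sp1]]
  prof <- mean_stage_profiles(s1$normalized, s1$design, ids = planted1,
                              map = s1$map)
  cl <- cluster_profiles(prof, k = 3)
  truth_class <- sim$truth$gene_profile[paste(sp1, names(cl$labels),
                                              sep = "|")]
  label_accuracy <- mean(cl$labels == unname(truth_class), na.rm = TRUE)

  # planted term enrichment on the detected concordant genes
  ann <- simulate_annotation(sim$truth, cfg)
  conc1 <- unique(unlist(lapply(res$concordance$detail, function(d)
    d$genes[[sp1]]), use.names = FALSE))
  bg <- sim$species[[sp1]]$annotation$accession
  er <- enrich(conc1, bg, ann)
  planted_term_q <- max(er$q[er$term %in% sim$truth$enriched_terms])

  sw <- res$sweep
  ids <- attr(sw, "group_ids")
  full_lab <- sw$subset[sw$n_species == length(cfg$species_names)]
  full_ids <- ids[[full_lab]]
  nested <- all(vapply(names(ids), function(lab)
    all(full_ids %in% ids[[lab]]), logical(1)))
  # along every chain S in S': the smaller subset keeps every group
  members <- strsplit(sw$subset, "+", fixed = TRUE)
  monotone <- TRUE
  for (i in seq_along(members)) for (j in seq_along(members)) {
    if (i == j || !all(members[[i]] %in% members[[j]])) next
    if (!(sw$n_groups[i] >= sw$n_groups[j] &&
          all(ids[[sw$subset[j]]] %in% ids[[sw$subset[i]]])))
      monotone <- FALSE
  }

  list(precision = pr$precision, recall = pr$recall,
       n_concordant = nrow(res$concordance$table),
       mcl_ari = ari, label_accuracy = label_accuracy,
       planted_term_q = planted_term_q,
       sweep = sw, sweep_nested = nested, sweep_monotone = monotone,
       config = cfg, result = res, truth = sim$truth)
}
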