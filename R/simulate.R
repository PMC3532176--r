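#' Configuration for the multi-species follicle-transcriptome simulator
#'
#' Describes a synthetic cross-species microarray study of the somatic
#' follicular cells at the three competence stages NC1, C1, C2: several
#' species, each with its own probe set, a minority of probes organised
#' into planted ortholog groups that carry a shared stage-effect profile,
#' multiplicative log-normal noise, and an i.i.d. per-spot dropout mask
#' standing in for spot flagging.
#'
#' Intensities are built on the log2 scale and exponentiated, since all
#' downstream statistics run on log2 values. Default replicate counts
#' (6, 14, 8) mirror the rainbow-trout design in which NC1, C1 and C2
#' follicles came from 6, 14 and 8 females.
#'
#' @param species_names labels of the simulated species.
#' @param n_probes_per_species probes (= genes, one probe per gene) per
#'   species.
#' @param n_planted_groups number of planted ortholog groups; every group
#'   has members in every species and one shared effect profile.
#' @param group_size_range integer `c(min, max)` genes per species per
#'   group (min >= 1; > 1 creates within-species in-paralogs).
#' @param effect_profiles named list of per-stage log2 offsets (unit
#'   scale), one numeric `c(NC1=, C1=, C2=)` per profile label.
#' @param effect_size multiplier applied to the profile offsets, in log2
#'   fold units (1 = two-fold).
#' @param noise_sd s.d. of the additive log2 noise.
#' @param replicates_per_stage integer `c(NC1=, C1=, C2=)` arrays per stage.
#' @param presence_dropout probability a spot is flagged absent, i.i.d.
#' @param n_terms number of annotation terms emitted by
#'   [simulate_annotation()].
#' @param enriched_term_fraction fraction of terms planted as enriched in
#'   the concordant genes.
#' @param seed integer seed governing all three generators.
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_experiment()], [simulate_similarity()],
#'   [simulate_annotation()]
#' @export
sim_config <- function(species_names = c("trout", "xenopus", "mouse", "cow"),
                       n_probes_per_species = 2000L,
                       n_planted_groups = 50L,
                       group_size_range = c(1L, 2L),
                       effect_profiles = list(
                         up_at_C2   = c(NC1 = 0, C1 = 0, C2 = 1),
                         down_at_C2 = c(NC1 = 0, C1 = 0, C2 = -1),
                         peak_at_C1 = c(NC1 = 0, C1 = 1, C2 = 0)),
                       effect_size = 1,
                       noise_sd = 0.35,
                       replicates_per_stage = c(NC1 = 6L, C1 = 14L, C2 = 8L),
                       presence_dropout = 0.02,
                       n_terms = 50L,
                       enriched_term_fraction = 0.1,
                       seed = 1L) {
  cfg <- list(species_names = as.character(species_names),
              n_probes_per_species = as.integer(n_probes_per_species),
              n_planted_groups = as.integer(n_planted_groups),
              group_size_range = as.integer(group_size_range),
              effect_profiles = effect_profiles,
              effect_size = effect_size,
              noise_sd = noise_sd,
              replicates_per_stage = replicates_per_stage,
              presence_dropout = presence_dropout,
              n_terms = as.integer(n_terms),
              enriched_term_fraction = enriched_term_fraction,
              seed = as.integer(seed))
  if (length(cfg$species_names) < 1 || anyDuplicated(cfg$species_names))
    stop("species_names must be non-empty and unique")
  if (cfg$n_probes_per_species < 1) stop("n_probes_per_species must be positive")
  if (cfg$n_planted_groups < 0) stop("n_planted_groups must be >= 0")
  if (length(cfg$group_size_range) != 2 || cfg$group_size_range[1] < 1 ||
      diff(cfg$group_size_range) < 0)
    stop("group_size_range must be c(min, max) with 1 <= min <= max")
  if (!length(cfg$effect_profiles) ||
      !all(vapply(cfg$effect_profiles,
                  function(p) all(STAGES %in% names(p)), logical(1))))
    stop("each effect profile needs named offsets for NC1, C1, C2")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (!all(STAGES %in% names(cfg$replicates_per_stage)) ||
      any(cfg$replicates_per_stage < 2))
    stop("replicates_per_stage needs >= 2 arrays for each of NC1, C1, C2")
  if (cfg$presence_dropout < 0 || cfg$presence_dropout >= 1)
    stop("presence_dropout must be in [0, 1)")
  if (cfg$n_terms < 0 || cfg$enriched_term_fraction < 0 ||
      cfg$enriched_term_fraction > 1)
    stop("invalid annotation settings")
  # worst case planted budget must fit the probe set
  if (cfg$n_planted_groups * cfg$group_size_range[2] > cfg$n_probes_per_species)
    stop("planted-gene budget exceeded: up to ",
         cfg$n_planted_groups * cfg$group_size_range[2],
         " planted genes per species but only ",
         cfg$n_probes_per_species, " probes")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d species, %d probes/species, ",
                     "%d planted groups, effect %.2g log2, noise sd %.2g\n"),
              length(x$species_names), x$n_probes_per_species,
              x$n_planted_groups, x$effect_size, x$noise_sd))
  invisible(x)
}

sim_accession <- function(species, i) {
  sprintf("%s_G%05d", toupper(species), i)
}

# Independent, reproducible sub-seeds: the i-th species' seed does not
# change when more species are appended, and auxiliary generators get
# their own streams.
sim_seeds <- function(seed, n_species) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, n_species + 2L)
  list(species = s[seq_len(n_species)],
       similarity = s[n_species + 1L],
       annotation = s[n_species + 2L])
}

#' Simulate a multi-species competence-stage expression study
#'
#' Generates, for every species in `cfg`, an [expression_matrix()] of
#' strictly positive intensities `2^(baseline + offset*effect_size +
#' N(0, noise_sd))` with a per-spot presence mask, the matching design
#' table, and a probe -> gene annotation table; plus a ground-truth record
#' of the planted ortholog groups, their effect-profile labels and the
#' term ids planted as enriched. Probes outside any planted group have
#' zero stage offset at every stage. Identical `cfg` (including its seed)
#' reproduces the output bit for bit.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `sim_experiment`: list with `species` (named
#'   list; each element has `expr`, `design`, `annotation`), `truth`
#'   (class `sim_truth`: `group_membership`, `group_profile`,
#'   `gene_profile`, `enriched_terms`, `seed`) and `config`.
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- sim_seeds(cfg$seed, length(cfg$species_names))
  n_groups <- cfg$n_planted_groups
  group_ids <- if (n_groups) sprintf("PG_%04d", seq_len(n_groups)) else character()
  profiles <- names(cfg$effect_profiles)
  # one shared profile per group, balanced deterministically
  group_profile <- if (n_groups)
    stats::setNames(profiles[(seq_len(n_groups) - 1L) %% length(profiles) + 1L],
                    group_ids) else stats::setNames(character(), character())

  reps <- cfg$replicates_per_stage[STAGES]
  stage_of_sample <- rep(STAGES, times = reps)
  membership <- stats::setNames(
    rep(list(data.frame(species = character(), gene = character(),
                        stringsAsFactors = FALSE)), n_groups), group_ids)
  gene_profile <- character()
  species_out <- list()

  for (si in seq_along(cfg$species_names)) {
    sp <- cfg$species_names[si]
    set.seed(seeds$species[si])
    n <- cfg$n_probes_per_species
    sizes <- if (n_groups)
      sample(seq(cfg$group_size_range[1], cfg$group_size_range[2]),
             n_groups, replace = TRUE) else integer()
    if (sum(sizes) > n)
      stop("planted-gene budget exceeded for species ", sp)
    probes <- sprintf("%s_p%05d", sp, seq_len(n))
    acc <- sim_accession(sp, seq_len(n))
    # planted genes occupy the head of the probe list, grouped contiguously
    offset_label <- rep(NA_character_, n)
    idx <- 0L
    for (gi in seq_len(n_groups)) {
      take <- seq_len(sizes[gi]) + idx
      idx <- idx + sizes[gi]
      gid <- group_ids[gi]
      membership[[gid]] <- rbind(
        membership[[gid]],
        data.frame(species = sp, gene = acc[take], stringsAsFactors = FALSE))
      offset_label[take] <- group_profile[gid]
      gene_profile[paste(sp, acc[take], sep = "|")] <- group_profile[gid]
    }
    samples <- sprintf("%s_%s_r%02d", sp, stage_of_sample,
                       unlist(lapply(reps, seq_len), use.names = FALSE))
    baseline <- stats::rnorm(n, mean = 8, sd = 2)
    offs <- matrix(0, n, length(samples))
    for (pf in profiles) {
      rows <- which(!is.na(offset_label) & offset_label == pf)
      if (length(rows)) {
        per_stage <- cfg$effect_profiles[[pf]][stage_of_sample] * cfg$effect_size
        offs[rows, ] <- matrix(per_stage, length(rows), length(samples),
                               byrow = TRUE)
      }
    }
    noise <- matrix(stats::rnorm(n * length(samples), sd = cfg$noise_sd),
                    n, length(samples))
    inten <- 2^(baseline + offs + noise)
    dimnames(inten) <- list(probes, samples)
    pres <- matrix(stats::runif(n * length(samples)) >= cfg$presence_dropout,
                   n, length(samples), dimnames = list(probes, samples))
    design <- data.frame(sample = samples, stage = stage_of_sample,
                         species = sp,
                         replicate = unlist(lapply(reps, seq_len),
                                            use.names = FALSE),
                         stringsAsFactors = FALSE)
    species_out[[sp]] <- list(
      expr = expression_matrix(inten, pres),
      design = design,
      annotation = data.frame(probe = probes, accession = acc,
                              stringsAsFactors = FALSE))
  }

  n_enriched <- max(0L, round(cfg$n_terms * cfg$enriched_term_fraction))
  terms <- if (cfg$n_terms) sprintf("TERM%04d", seq_len(cfg$n_terms)) else character()
  truth <- structure(list(group_membership = membership,
                          group_profile = group_profile,
                          gene_profile = gene_profile,
                          enriched_terms = utils::head(terms, n_enriched),
                          seed = cfg$seed),
                     class = "sim_truth")
  structure(list(species = species_out, truth = truth, config = cfg),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("sim_experiment: %d species x %d probes, %d planted groups\n",
              length(x$species), x$config$n_probes_per_species,
              length(x$truth$group_membership)))
  invisible(x)
}

#' Simulate all-vs-all protein similarity for a planted truth
#'
#' Emits a similarity table in the internal six-column form (see
#' [as_similarity()]): self-hits with e-value 0 for every gene in the
#' configured universe; strong hits (e-value `10^-U`, `U ~ Unif(50, 143)`
#' per unordered pair, each direction reporting it with a small
#' downward jitter so reciprocal e-values are near-symmetric, as in real
#' BLAST) for every cross-species pair within a planted group; stronger
#' still (`U ~ Unif(150, 178)`) for within-species group pairs, since
#' in-paralogs are post-speciation duplicates and must out-score every
#' cross-species hit to be recognisable as such; and, optionally,
#' spurious cross-group hits whose e-values stay at or above 1e-2 so
#' that any sensible threshold removes them. Planted e-values are
#' floored at 1e-180, far above double underflow.
#'
#' @param truth a `sim_truth` from [simulate_experiment()].
#' @param cfg the matching [sim_config()].
#' @param noise_hit_rate spurious cross-group hits emitted per planted
#'   in-group pair (0 disables them).
#' @return data.frame with columns `qspecies, qgene, sspecies, sgene,
#'   evalue, bitscore`, one row per direction.
#' @export
simulate_similarity <- function(truth, cfg, noise_hit_rate = 0.01) {
  stopifnot(inherits(truth, "sim_truth"), inherits(cfg, "sim_config"))
  seeds <- sim_seeds(cfg$seed, length(cfg$species_names))
  set.seed(seeds$similarity)

  uni_species <- rep(cfg$species_names, each = cfg$n_probes_per_species)
  uni_gene <- as.vector(vapply(cfg$species_names, function(sp)
    sim_accession(sp, seq_len(cfg$n_probes_per_species)),
    character(cfg$n_probes_per_species)))

  qs <- uni_species; qg <- uni_gene; ss <- uni_species; sg <- uni_gene
  ev <- rep(0, length(uni_gene)); bs <- rep(1000, length(uni_gene))

  add <- function(aqs, aqg, ass, asg, aev, abs_) {
    qs <<- c(qs, aqs); qg <<- c(qg, aqg)
    ss <<- c(ss, ass); sg <<- c(sg, asg)
    ev <<- c(ev, aev); bs <<- c(bs, abs_)
  }

  n_pairs <- 0L
  for (gid in names(truth$group_membership)) {
    mem <- truth$group_membership[[gid]]
    m <- nrow(mem)
    if (m < 2) next
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      cross <- mem$species[i] != mem$species[j]
      # one alignment strength per pair; the two directions report it
      # with a small jitter, so e-values are near-symmetric as in BLAST
      u <- if (cross) stats::runif(1, 50, 143) else stats::runif(1, 150, 178)
      for (dir in 1:2) {
        ud <- u + stats::runif(1, 0, 2)
        e <- max(10^-ud, 1e-180)
        qi <- if (dir == 1) i else j
        si <- if (dir == 1) j else i
        add(mem$species[qi], mem$gene[qi], mem$species[si], mem$gene[si],
            e, round(2 * ud + 40))
        n_pairs <- n_pairs + 1L
      }
    }
  }

  n_noise <- round(noise_hit_rate * n_pairs)
  if (n_noise > 0) {
    i <- sample.int(length(uni_gene), n_noise, replace = TRUE)
    j <- sample.int(length(uni_gene), n_noise, replace = TRUE)
    keep <- i != j
    u <- stats::runif(sum(keep), 0, 2)   # e-values in [1e-2, 1]
    add(uni_species[i[keep]], uni_gene[i[keep]],
        uni_species[j[keep]], uni_gene[j[keep]],
        10^-u, round(2 * u + 20))
  }
  data.frame(qspecies = qs, qgene = qg, sspecies = ss, sgene = sg,
             evalue = ev, bitscore = bs, stringsAsFactors = FALSE)
}

#' Simulate a GMT term annotation with planted enrichment
#'
#' Builds a term -> gene annotation over one species' gene universe.
#' Terms listed in `truth$enriched_terms` include each planted
#' (ortholog-group) gene with probability `p_planted` and each background
#' gene with probability `p_background`; all other terms sample uniformly
#' at `p_background`. Setting `p_planted = p_background` yields a null
#' annotation in which no term is enriched beyond chance.
#'
#' @param truth a `sim_truth`.
#' @param cfg the matching [sim_config()].
#' @param species species whose gene namespace the GMT uses (default:
#'   first configured species).
#' @param p_planted inclusion probability of planted genes in enriched
#'   terms.
#' @param p_background inclusion probability of any gene in ordinary
#'   terms (and of background genes in enriched terms).
#' @return named list, term id -> character vector of gene accessions
#'   (GMT form, see [write_gmt()]).
#' @export
simulate_annotation <- function(truth, cfg, species = cfg$species_names[1],
                                p_planted = 0.8, p_background = 0.05) {
  stopifnot(inherits(truth, "sim_truth"), inherits(cfg, "sim_config"))
  if (cfg$n_probes_per_species < 1L)
    stop("empty gene universe")
  seeds <- sim_seeds(cfg$seed, length(cfg$species_names))
  set.seed(seeds$annotation)
  universe <- sim_accession(species, seq_len(cfg$n_probes_per_species))
  planted <- unlist(lapply(truth$group_membership, function(m)
    m$gene[m$species == species]), use.names = FALSE)
  background <- setdiff(universe, planted)
  terms <- sprintf("TERM%04d", seq_len(cfg$n_terms))
  out <- list()
  for (tm in terms) {
    if (tm %in% truth$enriched_terms) {
      g <- c(planted[stats::runif(length(planted)) < p_planted],
             background[stats::runif(length(background)) < p_background])
    } else {
      g <- universe[stats::runif(length(universe)) < p_background]
    }
    out[[tm]] <- g
  }
  out
}

#' Write / read a simulation ground truth as JSON
#'
#' Serialises the planted structure (group membership, profile labels,
#' enriched terms, seed) so that a simulated study written to disk stays
#' self-describing.
#'
#' @param truth a `sim_truth`.
#' @param path file path.
#' @return `read_truth_json`: the `sim_truth`.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  obj <- list(
    group_membership = lapply(truth$group_membership, function(m)
      paste(m$species, m$gene, sep = "|")),
    group_profile = as.list(truth$group_profile),
    gene_profile = as.list(truth$gene_profile),
    enriched_terms = truth$enriched_terms,
    seed = truth$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  membership <- lapply(obj$group_membership, function(keys) {
    parts <- split_taxon_id(unlist(keys))
    data.frame(species = parts$species, gene = parts$gene,
               stringsAsFactors = FALSE)
  })
  structure(list(group_membership = membership,
                 group_profile = unlist(obj$group_profile),
                 gene_profile = unlist(obj$gene_profile),
                 enriched_terms = unlist(obj$enriched_terms),
                 seed = obj$seed),
            class = "sim_truth")
}
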