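# Brute-force witness oracle: enumerate all (pair, sign) combinations and
# check each against every species' member-gene calls directly.
screen_oracle <- function(groups, calls, subset, same_pair = TRUE) {
  pairs <- c("NC1:C1", "C1:C2", "NC1:C2")
  out <- character()
  for (gid in unique(groups$group_id)) {
    ok <- FALSE
    if (same_pair) {
      for (pr in pairs) for (sg in c(1, -1)) {
        hit_all <- all(vapply(subset, function(sp) {
          genes <- groups$gene[groups$group_id == gid & groups$species == sp]
          cl <- calls[[sp]]
          any(cl$gene %in% genes & cl$pair == pr & cl$sign == sg)
        }, logical(1)))
        if (hit_all) ok <- TRUE
      }
    } else {
      for (sg in c(1, -1)) {
        hit_all <- all(vapply(subset, function(sp) {
          genes <- groups$gene[groups$group_id == gid & groups$species == sp]
          cl <- calls[[sp]]
          any(cl$gene %in% genes & cl$sign == sg)
        }, logical(1)))
        if (hit_all) ok <- TRUE
      }
    }
    if (ok) out <- c(out, gid)
  }
  out
}

test_that("the concordance screen finds shared (pair, sign) witnesses", {
  groups <- groups_df(c("trout|g1", "xenopus|g2"),
                      c("trout|g3", "xenopus|g4"),
                      c("trout|g5", "xenopus|g6"))
  calls <- list(
    trout = calls_df(c("g1", "g3", "g5"), c("C1:C2", "C1:C2", "NC1:C1"),
                     c(1, 1, 1)),
    xenopus = calls_df(c("g2", "g4", "g6"), c("C1:C2", "C1:C2", "C1:C2"),
                       c(1, -1, 1)))
  sc <- screen_concordance(groups, calls)
  expect_identical(sc$table$group_id, "G01")
  expect_identical(sc$detail$G01$witnesses$pair, "C1:C2")
  expect_equal(sc$detail$G01$witnesses$sign, 1)
  expect_identical(sc$detail$G01$genes$trout, "g1")
  # opposite signs on the same pair are discordant (G02); different pairs
  # with the same sign (G03) qualify only under the loose rule
  loose <- screen_concordance(groups, calls, require_same_pair = FALSE)
  expect_setequal(loose$table$group_id, c("G01", "G03"))
  expect_error(screen_concordance(groups, calls, c("trout", "mouse")),
               "trout|mouse")
})

test_that("screen matches the brute-force oracle on random toy instances", {
  set.seed(404)
  species <- c("s1", "s2", "s3")
  pairs <- c("NC1:C1", "C1:C2", "NC1:C2")
  for (trial in 1:25) {
    # random groups of <= 6 genes over 3 species
    n_g <- sample(2:5, 1)
    rows <- list()
    gene_ctr <- 0
    for (gi in seq_len(n_g)) {
      for (sp in species) {
        for (m in seq_len(sample(0:2, 1))) {
          gene_ctr <- gene_ctr + 1
          rows[[length(rows) + 1L]] <- data.frame(
            group_id = sprintf("G%02d", gi), species = sp,
            gene = sprintf("g%03d", gene_ctr), stringsAsFactors = FALSE)
        }
      }
    }
    groups <- do.call(rbind, rows)
    calls <- lapply(stats::setNames(species, species), function(sp) {
      genes <- groups$gene[groups$species == sp]
      picked <- genes[runif(length(genes)) < 0.7]
      if (!length(picked)) return(calls_df(character(), character(), numeric()))
      k <- lengths(list(picked))
      calls_df(rep(picked, each = 1),
               sample(pairs, length(picked), replace = TRUE),
               sample(c(1, -1), length(picked), replace = TRUE))
    })
    groups_cov <- groups[groups$species %in% species, ]
    if (!all(species %in% groups$species)) next
    for (same in c(TRUE, FALSE)) {
      got <- screen_concordance(groups, calls, species,
                                require_same_pair = same)
      want <- screen_oracle(groups, calls, species, same_pair = same)
      expect_setequal(got$table$group_id, want)
    }
  }
})

test_that("screen output is invariant to row order", {
  groups <- groups_df(c("a|g1", "a|g2", "b|g3"), c("a|g4", "b|g5"))
  calls <- list(a = calls_df(c("g1", "g2", "g4"), rep("NC1:C2", 3),
                             c(1, -1, 1)),
                b = calls_df(c("g3", "g5"), c("NC1:C2", "C1:C2"), c(1, 1)))
  s1 <- screen_concordance(groups, calls)
  s2 <- screen_concordance(groups[rev(seq_len(nrow(groups))), ],
                           lapply(calls, function(cl)
                             cl[rev(seq_len(nrow(cl))), ]))
  expect_identical(s1$table, s2$table)
})

test_that("subset sweep counts are monotone and nested", {
  set.seed(70)
  cfg <- sim_config(n_probes_per_species = 300, n_planted_groups = 20,
                    group_size_range = c(1, 1), seed = 70)
  sim <- simulate_experiment(cfg)
  rec <- simulate_similarity(sim$truth, cfg)
  calls <- lapply(sim$species, function(s) {
    de <- call_de(s$expr, s$design)
    dirs <- pairwise_directions(s$expr, s$design, de)
    probe_to_gene_directions(dirs, map_probes_direct(s$annotation))
  })
  groups <- infer_ortholog_groups(rec)
  sw <- subset_sweep(groups, calls)
  ids <- attr(sw, "group_ids")
  full <- ids[["trout+xenopus+mouse+cow"]]
  for (lab in names(ids)) {
    sub <- strsplit(lab, "+", fixed = TRUE)[[1]]
    # a group concordant for a superset is concordant for the subset
    expect_true(all(full %in% ids[[lab]]))
  }
  # counts non-increasing in subset size
  by_size <- tapply(sw$n_groups, sw$n_species, max)
  expect_true(all(diff(by_size) <= 0) ||
                max(sw$n_groups[sw$n_species == 4]) <=
                min(sw$n_groups[sw$n_species == 2]))
  # every 3-subset count >= the 4-subset count
  expect_true(all(sw$n_groups[sw$n_species == 3] >=
                    sw$n_groups[sw$n_species == 4]))
})

test_that("sweep on groups with no calls reports zeros", {
  groups <- groups_df(c("a|g1", "b|g2"))
  calls <- list(a = calls_df(character(), character(), numeric()),
                b = calls_df(character(), character(), numeric()))
  sw <- subset_sweep(groups, calls)
  expect_true(all(sw$n_groups == 0))
})

test_that("mean stage profiles and their standardization", {
  # 2 samples per stage, noiseless: probe means are exact
  design <- toy_design(c(NC1 = 2, C1 = 2, C2 = 2))
  m <- rbind(2^c(1, 1, 2, 2, 3, 3),    # profile (1,2,3)
             2^c(5, 5, 5, 5, 5, 5))    # constant
  x <- toy_matrix(m)
  pr <- mean_stage_profiles(x, design)
  expect_equal(unname(pr$mean["p01", ]), c(1, 2, 3))
  expect_equal(unname(pr$z["p01", ]), c(-1.224745, 0, 1.224745),
               tolerance = 1e-6)
  expect_equal(unname(pr$z["p02", ]), c(0, 0, 0))
})

test_that("gene-level profiles pool probes through the map", {
  design <- toy_design(c(NC1 = 2, C1 = 2, C2 = 2))
  m <- rbind(2^c(1, 1, 2, 2, 3, 3), 2^c(3, 3, 4, 4, 5, 5))
  x <- toy_matrix(m)
  map <- data.frame(probe = c("p01", "p02"), accession = c("A", "A"))
  pr <- mean_stage_profiles(x, design, map = map)
  expect_equal(unname(pr$mean["A", ]), c(2, 3, 4))
  # an empty stage drops the profile with a warning
  pres <- matrix(TRUE, 2, 6); pres[2, 3:4] <- FALSE
  x2 <- toy_matrix(m, presence = pres)
  expect_warning(pr2 <- mean_stage_profiles(x2, design), "dropped")
  expect_identical(rownames(pr2$mean), "p01")
})

test_that("profile distance is 1 - centred Pearson", {
  design <- toy_design(c(NC1 = 2, C1 = 2, C2 = 2))
  m <- rbind(2^c(1, 1, 2, 2, 3, 3), 2^c(3, 3, 2, 2, 1, 1))
  pr <- mean_stage_profiles(toy_matrix(m), design)
  D <- orthoscreen:::profile_distance(pr$z)
  expect_equal(D[1, 2], 2, tolerance = 1e-12)   # (1,2,3) vs (3,2,1)
  expect_equal(D[1, 1], 0)
})

test_that("profile clustering separates shapes and labels them", {
  design <- toy_design(c(NC1 = 2, C1 = 2, C2 = 2))
  up <- t(replicate(6, 2^c(1, 1, 1, 1, 3, 3)))
  down <- t(replicate(6, 2^c(3, 3, 3, 3, 1, 1)))
  peak <- t(replicate(6, 2^c(1, 1, 3, 3, 1, 1)))
  x <- toy_matrix(rbind(up, down, peak))
  pr <- mean_stage_profiles(x, design)
  cl <- cluster_profiles(pr, k = 3)
  expect_setequal(unique(cl$labels[1:6]), "up_at_C2")
  expect_setequal(unique(cl$labels[7:12]), "down_at_C2")
  expect_setequal(unique(cl$labels[13:18]), "peak_at_C1")
  # antipodal shapes with k = 2 split perfectly
  x2 <- toy_matrix(rbind(up, down))
  cl2 <- cluster_profiles(mean_stage_profiles(x2, design), k = 2)
  expect_equal(length(unique(cl2$cluster[1:6])), 1)
  expect_equal(length(unique(cl2$cluster[7:12])), 1)
  expect_false(cl2$cluster[1] == cl2$cluster[7])
  # identical profiles merge first, at height 0
  expect_equal(min(cl$hclust$height), 0, tolerance = 1e-12)
  # all-flat input degenerates to one 'flat' cluster
  flat <- toy_matrix(matrix(4, 4, 6))
  clf <- cluster_profiles(mean_stage_profiles(flat, design))
  expect_equal(clf$k, 1L)
  expect_setequal(unique(clf$labels), "flat")
})

test_that("noiseless planted genes cluster into their planted classes", {
  cfg <- sim_config(species_names = "sp", n_probes_per_species = 120,
                    n_planted_groups = 30, group_size_range = c(1, 1),
                    noise_sd = 0, presence_dropout = 0, seed = 41)
  sim <- simulate_experiment(cfg)
  planted <- sprintf("sp_p%05d", 1:30)
  pr <- mean_stage_profiles(sim$species$sp$expr, sim$species$sp$design,
                            ids = planted)
  cl <- cluster_profiles(pr, k = 3)
  truth <- sim$truth$gene_profile[paste0("sp|",
                                         sim$species$sp$annotation$accession[1:30])]
  got <- cl$labels[planted]
  expect_gte(mean(got == unname(truth)), 0.95)
})
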