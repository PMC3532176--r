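# Independent MCL oracle: dense power iteration with inflation, run to a
# fixed point with no pruning; clusters read as connected components of
# the thresholded limit matrix.
mcl_oracle <- function(nodes, edges, inflation, loops = 1) {
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    A[edges$node_a[i], edges$node_b[i]] <- edges$weight[i]
    A[edges$node_b[i], edges$node_a[i]] <- edges$weight[i]
  }
  diag(A) <- diag(A) + loops
  M <- sweep(A, 2, colSums(A), `/`)
  for (it in 1:5000) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- sweep(M2, 2, colSums(M2), `/`)
    if (max(abs(M2 - M)) < 1e-12) { M <- M2; break }
    M <- M2
  }
  sup <- (M > 1e-8) | t(M > 1e-8)
  g <- igraph::graph_from_adjacency_matrix(sup, mode = "undirected")
  split(nodes, igraph::components(g)$membership)
}

as_member_sets <- function(groups) {
  unname(lapply(split(paste(groups$species, groups$gene, sep = "|"),
                      groups$group_id), sort))
}

test_that("reciprocal best hits require mutual best and honour ties", {
  rec <- rbind(sim_pair("A", "a1", "B", "b1", 1e-50),
               sim_pair("A", "a2", "B", "b2", 1e-40))
  got <- rbh_pairs(rec, "A", "B")
  expect_equal(got$gene_a, c("a1", "a2"))
  # a1 -> b1 best, but b1's best is a2: no pair for a1
  rec2 <- rbind(sim_row("A", "a1", "B", "b1", 1e-50),
                sim_row("B", "b1", "A", "a2", 1e-60),
                sim_row("B", "b1", "A", "a1", 1e-50),
                sim_row("A", "a2", "B", "b1", 1e-60))
  got2 <- rbh_pairs(rec2, "A", "B")
  expect_identical(got2$gene_a, "a2")
  # equal e-values: bitscore 100 beats 90, regardless of record order
  rec3 <- rbind(sim_row("A", "a1", "B", "b1", 1e-30, bit = 100),
                sim_row("A", "a1", "B", "b2", 1e-30, bit = 90),
                sim_row("B", "b1", "A", "a1", 1e-30, bit = 100),
                sim_row("B", "b2", "A", "a1", 1e-30, bit = 90))
  for (perm in list(1:4, 4:1, c(2, 4, 1, 3))) {
    got3 <- rbh_pairs(rec3[perm, ], "A", "B")
    expect_identical(got3$gene_b, "b1")
  }
  # sub-threshold filtering
  expect_equal(nrow(rbh_pairs(sim_pair("A", "a1", "B", "b1", 1e-2),
                              "A", "B")), 0)
})

test_that("rbh_pairs is invariant to uniform bitscore scaling", {
  set.seed(55)
  rec <- do.call(rbind, lapply(1:20, function(i)
    sim_row(sample(c("A", "B"), 1), sprintf("g%da", i),
            sample(c("A", "B"), 1), sprintf("g%db", i),
            10^-runif(1, 1, 50), bit = runif(1, 50, 500))))
  rec2 <- rec
  rec2$bitscore <- rec2$bitscore * 7
  expect_identical(rbh_pairs(rec, "A", "B"), rbh_pairs(rec2, "A", "B"))
})

test_that("in-paralog edges require dominance over cross-species hits and an anchor", {
  base <- rbind(sim_pair("A", "a1", "B", "b1", 1e-80),   # anchor for a1
                sim_pair("A", "a1", "A", "a2", 1e-150))  # close duplicate
  inp <- find_inparalogs(base, "A", "a1")
  expect_equal(nrow(inp), 1)
  expect_identical(inp$gene_a, "a1")
  expect_equal(inp$mutual_evalue, 1e-150)
  # weaker than the cross-species best: no edge
  weak <- rbind(sim_pair("A", "a1", "B", "b1", 1e-80),
                sim_pair("A", "a1", "A", "a2", 1e-40))
  expect_equal(nrow(find_inparalogs(weak, "A", "a1")), 0)
  # species with no cross-species hits at all: nothing anchors
  iso <- sim_pair("C", "c1", "C", "c2", 1e-150)
  expect_equal(nrow(find_inparalogs(iso, "C", character())), 0)
})

test_that("graph weights use -log10 e-values, the zero cap, and class means", {
  rbh <- rbind(
    data.frame(species_a = "A", gene_a = "a1", species_b = "B", gene_b = "b1",
               evalue_ab = 1e-50, evalue_ba = 1e-50),
    data.frame(species_a = "A", gene_a = "a2", species_b = "B", gene_b = "b2",
               evalue_ab = 0, evalue_ba = 0),
    data.frame(species_a = "A", gene_a = "a3", species_b = "C", gene_b = "c1",
               evalue_ab = 1e-40, evalue_ba = 1e-60))
  g <- build_graph(rbh)
  expect_equal(g$raw_weight, c(50, 300, 50))
  # class means: A:B edges (50, 300) -> mean 175; A:C edge 50 -> mean 50
  expect_equal(g$weight, c(50 / 175, 300 / 175, 1))
  ab <- g$class_key == "A:B"
  expect_equal(mean(g$weight[ab]), 1)
  expect_equal(mean(g$weight[!ab]), 1)
  # in-paralog edges are normalized per species, separately
  inp <- data.frame(species = "A", gene_a = "a1", gene_b = "a2",
                    evalue_ab = 1e-100, evalue_ba = 1e-100,
                    mutual_evalue = 1e-100)
  g2 <- build_graph(rbh, inp)
  expect_equal(g2$weight[g2$category == "inparalog"], 1)
})

test_that("mcl separates disconnected components and isolated nodes", {
  tri <- function(sp, pre) {
    nodes <- paste0(pre, 1:3)
    do.call(rbind, lapply(list(c(1, 2), c(1, 3), c(2, 3)), function(ij)
      data.frame(node_a = paste(sp, nodes[ij[1]], sep = "|"),
                 node_b = paste(sp, nodes[ij[2]], sep = "|"),
                 weight = 1, stringsAsFactors = FALSE)))
  }
  g <- rbind(tri("A", "x"), tri("B", "y"),
             data.frame(node_a = "C|lone", node_b = "C|lone", weight = 1))
  got <- mcl(g, inflation = 2)
  sets <- as_member_sets(got)
  expect_setequal(sets, list(c("A|x1", "A|x2", "A|x3"),
                             c("B|y1", "B|y2", "B|y3"), "C|lone"))
})

test_that("mcl splits a weakly-joined barbell exactly as the oracle does", {
  k4 <- function(pre) {
    nodes <- paste0("S|", pre, 1:4)
    cmb <- utils::combn(4, 2)
    data.frame(node_a = nodes[cmb[1, ]], node_b = nodes[cmb[2, ]],
               weight = 1, stringsAsFactors = FALSE)
  }
  bar <- rbind(k4("l"), k4("r"),
               data.frame(node_a = "S|l1", node_b = "S|r1", weight = 0.1))
  got <- mcl(bar, inflation = 2)
  sets <- as_member_sets(got)
  nodes <- sort(unique(c(bar$node_a, bar$node_b)))
  want <- unname(lapply(mcl_oracle(nodes, bar, inflation = 2), sort))
  expect_setequal(sets, want)
  expect_equal(lengths(sets), c(4, 4))
})

test_that("mcl agrees with the dense power-iteration oracle on random graphs", {
  set.seed(303)
  for (trial in 1:8) {
    n <- sample(6:12, 1)
    nodes <- paste0("S|n", sprintf("%02d", seq_len(n)))
    # two planted communities with sparse cross edges
    half <- n %/% 2
    edges <- list()
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i >= j) next
      same <- (i <= half) == (j <= half)
      pr <- if (same) 0.9 else 0.15
      if (runif(1) < pr)
        edges[[length(edges) + 1L]] <- data.frame(
          node_a = nodes[i], node_b = nodes[j],
          weight = if (same) runif(1, 0.8, 1.2) else runif(1, 0.05, 0.15),
          stringsAsFactors = FALSE)
    }
    if (!length(edges)) next
    e <- do.call(rbind, edges)
    got <- as_member_sets(mcl(e, inflation = 2))
    present <- sort(unique(c(e$node_a, e$node_b)))
    want <- unname(lapply(mcl_oracle(present, e, inflation = 2), sort))
    expect_setequal(got, want)
  }
})

test_that("mcl output is a partition and is label-equivariant", {
  set.seed(21)
  cfg <- sim_config(species_names = c("a", "b", "c"),
                    n_probes_per_species = 120, n_planted_groups = 12,
                    seed = 21)
  sim <- simulate_experiment(cfg)
  rec <- simulate_similarity(sim$truth, cfg)
  groups <- infer_ortholog_groups(rec)
  key <- paste(groups$species, groups$gene, sep = "|")
  expect_false(anyDuplicated(key) > 0)                  # disjoint
  expect_setequal(unique(groups$species), c("a", "b", "c"))
  # label permutation: renaming genes permutes the partition identically
  rec2 <- rec
  relab <- function(g) sub("G000", "H000", g, fixed = TRUE)
  rec2$qgene <- relab(rec2$qgene); rec2$sgene <- relab(rec2$sgene)
  g2 <- infer_ortholog_groups(rec2)
  expect_setequal(
    as_member_sets(g2),
    lapply(as_member_sets(groups), function(s) sort(relab(s))))
})

test_that("planted orthology is recovered near-perfectly (adjusted Rand)", {
  cfg <- sim_config(species_names = c("a", "b", "c"),
                    n_probes_per_species = 400, n_planted_groups = 100,
                    group_size_range = c(1, 2), seed = 99)
  sim <- simulate_experiment(cfg)
  rec <- simulate_similarity(sim$truth, cfg)   # default spurious-hit rate
  groups <- infer_ortholog_groups(rec)
  truth_lab <- unlist(lapply(names(sim$truth$group_membership), function(g) {
    m <- sim$truth$group_membership[[g]]
    stats::setNames(rep(g, nrow(m)), paste(m$species, m$gene, sep = "|"))
  }))
  got_lab <- stats::setNames(groups$group_id,
                             paste(groups$species, groups$gene, sep = "|"))
  common <- names(truth_lab)
  ari <- mclust::adjustedRandIndex(truth_lab[common], got_lab[common])
  expect_gte(ari, 0.95)
})

test_that("groups.txt parsing follows the OrthoMCL dialect", {
  g <- load_groups(text = "OG_10201: mmu|Tnfrsf23 bta|TNFRSF23")
  expect_equal(nrow(g), 2)
  expect_identical(g$group_id, rep("OG_10201", 2))
  expect_identical(g$gene, c("Tnfrsf23", "TNFRSF23"))
  expect_equal(nrow(load_groups(text = character())), 0)
  # duplicates inside one group are dropped silently
  d <- load_groups(text = "G1: a|x a|x b|y")
  expect_equal(nrow(d), 2)
  # a gene in two groups breaks the partition invariant
  expect_error(load_groups(text = c("G1: a|x b|y", "G2: a|x c|z")),
               "more than one group")
  expect_error(load_groups(text = c("G1: a|x", "garbage line")),
               "line 2")
  # round-trip through a file
  f <- tempfile(fileext = ".txt")
  write_groups(g, f)
  expect_identical(load_groups(f), g)
})
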