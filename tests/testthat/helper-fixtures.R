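# Small in-code fixtures shared across test files.

# Tiny expression matrix: probes x samples with explicit values.
toy_matrix <- function(values, probes = NULL, samples = NULL,
                       presence = NULL) {
  m <- as.matrix(values)
  if (is.null(probes)) probes <- sprintf("p%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(probes, samples)
  if (!is.null(presence)) dimnames(presence) <- dimnames(m)
  expression_matrix(m, presence)
}

# Design with n replicates per stage, samples named to match toy_matrix.
toy_design <- function(n_per_stage = c(NC1 = 2, C1 = 2, C2 = 2),
                       species = "sp1") {
  stages <- rep(names(n_per_stage), times = n_per_stage)
  data.frame(sample = sprintf("s%02d", seq_along(stages)), stage = stages,
             species = species,
             replicate = unlist(lapply(n_per_stage, seq_len),
                                use.names = FALSE),
             stringsAsFactors = FALSE)
}

# Similarity row constructor for hand-built orthology toys.
sim_row <- function(qs, qg, ss, sg, e, bit = 100) {
  data.frame(qspecies = qs, qgene = qg, sspecies = ss, sgene = sg,
             evalue = e, bitscore = bit, stringsAsFactors = FALSE)
}

# Symmetric pair of similarity rows.
sim_pair <- function(sa, ga, sb, gb, e_ab, e_ba = e_ab, bit = 100) {
  rbind(sim_row(sa, ga, sb, gb, e_ab, bit), sim_row(sb, gb, sa, ga, e_ba, bit))
}

# A gene-level direction-call frame.
calls_df <- function(gene, pair, sign) {
  parts <- strsplit(pair, ":", fixed = TRUE)
  data.frame(gene = gene, earlier = vapply(parts, `[`, "", 1),
             later = vapply(parts, `[`, "", 2), pair = pair, sign = sign,
             pair_p = rep(0.01, length(gene)), fold_change = 2^sign,
             stringsAsFactors = FALSE)
}

# Long-format ortholog group frame from "sp|gene" member strings.
groups_df <- function(...) {
  gl <- list(...)
  out <- lapply(seq_along(gl), function(i) {
    sp <- sub("\\|.*", "", gl[[i]])
    g <- sub("^[^|]*\\|", "", gl[[i]])
    data.frame(group_id = sprintf("G%02d", i), species = sp, gene = g,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
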