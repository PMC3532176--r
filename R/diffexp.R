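#' One-way fixed-effects ANOVA F test
#'
#' Classical one-factor ANOVA, `F = MS_between / MS_within` on
#' `(k - 1, n - k)` degrees of freedom, for `k >= 2` groups of log2
#' intensities. Degenerate inputs are resolved explicitly: when every
#' group has zero within-group variance, equal means give `F = 0, p = 1`
#' and unequal means give `F = Inf, p = 0`.
#'
#' @param groups list of >= 2 numeric vectors, each with >= 2 values.
#' @return list with elements `F`, `p`, `df` (`c(df1, df2)`).
#' @examples
#' anova_f(list(c(1, 2, 3), c(2, 3, 4), c(5, 6, 7)))  # F = 13
#' @export
anova_f <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2))
    stop("each group needs >= 2 values")
  k <- length(groups)
  n <- sum(sizes)
  df <- c(k - 1, n - k)
  vars <- vapply(groups, stats::var, numeric(1))
  means <- vapply(groups, mean, numeric(1))
  if (all(vars == 0)) {
    if (max(means) - min(means) == 0)
      return(list(F = 0, p = 1, df = df))
    return(list(F = Inf, p = 0, df = df))
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_len(k), sizes))
  ow <- stats::oneway.test(y ~ g, var.equal = TRUE)
  F <- unname(ow$statistic)
  if (is.nan(F)) return(list(F = 0, p = 1, df = df))
  if (!is.finite(F)) return(list(F = Inf, p = 0, df = df))
  list(F = F, p = unname(ow$p.value), df = df)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, `q_(i) = min_(j>=i) p_(j) * m / j` clipped at
#' 1 and mapped back to input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of adjusted p-values, same order as input.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric())
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

# Split a probe's log2 present values by stage; keep stages with enough
# replicates.
stage_values <- function(logm_row, design, min_present = 2L) {
  vals <- split(logm_row, design$stage)
  vals <- lapply(vals, function(v) v[!is.na(v)])
  vals[lengths(vals) >= min_present]
}

#' Per-probe differential-expression calls (ANOVA + BH)
#'
#' Runs the one-factor ANOVA across the NC1/C1/C2 stage groups on log2
#' present intensities for every probe, applies the Benjamini-Hochberg
#' correction over the tested probes, and flags significance at adjusted
#' p < `alpha` (default 0.01, the study-wide cutoff). Probes lacking
#' `min_present` present replicates in at least two stages are skipped
#' with a recorded reason rather than tested.
#'
#' @param x a preprocessed [expression_matrix()].
#' @param design design table for `x` (one species).
#' @param alpha significance level on the adjusted p-value.
#' @param min_present minimum present replicates per stage group.
#' @return data.frame with one row per probe: `probe`, `n_stages`, `F`,
#'   `p`, `q`, `significant`, `reason` (NA when tested).
#' @export
call_de <- function(x, design, alpha = 0.01, min_present = 2L) {
  stopifnot(inherits(x, "expr_matrix"))
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  design <- validate_design(design, x)
  if (nlevels(droplevels(design$stage)) < 2)
    stop("need >= 2 stages with samples")
  logm <- log2_present(x)
  n <- nrow(logm)
  Fv <- pv <- rep(NA_real_, n)
  ns <- integer(n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    gr <- stage_values(logm[i, ], design, min_present)
    ns[i] <- length(gr)
    if (length(gr) < 2) {
      reason[i] <- "insufficient_present_replicates"
      next
    }
    a <- anova_f(gr)
    Fv[i] <- a$F
    pv[i] <- a$p
  }
  q <- rep(NA_real_, n)
  tested <- is.na(reason)
  if (any(tested)) q[tested] <- bh_adjust(pv[tested])
  data.frame(probe = rownames(logm), n_stages = ns, F = Fv, p = pv, q = q,
             significant = !is.na(q) & q < alpha, reason = reason,
             stringsAsFactors = FALSE)
}

#' Per-stage-pair direction calls for significant probes
#'
#' For every ANOVA-significant probe and each ordered stage pair
#' (NC1,C1), (C1,C2), (NC1,C2), emits a direction call when the Welch
#' two-sample t test on log2 present values has p < `pair_alpha`. The
#' sign is the sign of the later-minus-earlier mean log2 difference and
#' the fold change is `2^difference` (linear ratio later/earlier).
#' `pair_alpha = 1` degrades gracefully to reading directions off the
#' stage means alone. Stages with fewer than `min_present` present values
#' are skipped for that pair.
#'
#' @param x a preprocessed [expression_matrix()].
#' @param design design table for `x`.
#' @param de result of [call_de()] on the same matrix.
#' @param pair_alpha per-pair significance level (default 0.05).
#' @param min_present minimum present replicates per side.
#' @return data.frame with columns `probe`, `earlier`, `later`, `pair`,
#'   `sign`, `pair_p`, `fold_change`.
#' @export
pairwise_directions <- function(x, design, de, pair_alpha = 0.05,
                                min_present = 2L) {
  stopifnot(inherits(x, "expr_matrix"))
  if (pair_alpha <= 0 || pair_alpha > 1) stop("pair_alpha must be in (0, 1]")
  design <- validate_design(design, x)
  logm <- log2_present(x)
  sig <- de$probe[de$significant]
  sig <- intersect(sig, rownames(logm))
  out <- vector("list", length(sig) * length(STAGE_PAIRS))
  kk <- 0L
  stage_cols <- lapply(stats::setNames(STAGES, STAGES), function(st)
    which(design$stage == st))
  for (pr in sig) {
    row <- logm[pr, ]
    for (sp in STAGE_PAIRS) {
      a <- row[stage_cols[[sp[1]]]]; a <- a[!is.na(a)]
      b <- row[stage_cols[[sp[2]]]]; b <- b[!is.na(b)]
      if (length(a) < min_present || length(b) < min_present) next
      d <- mean(b) - mean(a)
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        p <- if (d == 0) 1 else 0
      } else {
        p <- stats::t.test(b, a)$p.value   # Welch by default
      }
      if (p < pair_alpha && d != 0) {
        kk <- kk + 1L
        out[[kk]] <- data.frame(probe = pr, earlier = sp[1], later = sp[2],
                                pair = pair_label(sp[1], sp[2]),
                                sign = sign(d), pair_p = p,
                                fold_change = 2^d, stringsAsFactors = FALSE)
      }
    }
  }
  if (!kk)
    return(data.frame(probe = character(), earlier = character(),
                      later = character(), pair = character(),
                      sign = numeric(), pair_p = numeric(),
                      fold_change = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out[seq_len(kk)])
}

#' Lift probe-level direction calls to gene level
#'
#' Genes inherit the union of their probes' calls through a probe-gene
#' map. When several probes of one gene disagree in sign on the same
#' stage pair, the majority sign wins; an exact tie drops the call for
#' that (gene, pair) and records it in the `ties` attribute. The reported
#' `pair_p` is the smallest p among the agreeing probes and the fold
#' change their geometric mean.
#'
#' @param calls probe-level calls from [pairwise_directions()].
#' @param map probe-gene map (columns `probe`, `accession`).
#' @return data.frame with columns `gene`, `earlier`, `later`, `pair`,
#'   `sign`, `pair_p`, `fold_change`, `n_probes`.
#' @export
probe_to_gene_directions <- function(calls, map) {
  merged <- merge(calls, map[c("probe", "accession")], by = "probe")
  empty <- data.frame(gene = character(), earlier = character(),
                      later = character(), pair = character(),
                      sign = numeric(), pair_p = numeric(),
                      fold_change = numeric(), n_probes = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(merged)) {
    attr(empty, "ties") <- empty[0, c("gene", "pair")]
    return(empty)
  }
  pieces <- split(merged, list(merged$accession, merged$pair), drop = TRUE)
  rows <- vector("list", length(pieces))
  ties <- list()
  for (i in seq_along(pieces)) {
    pc <- pieces[[i]]
    net <- sum(pc$sign)
    if (net == 0) {
      ties[[length(ties) + 1L]] <- data.frame(gene = pc$accession[1],
                                              pair = pc$pair[1],
                                              stringsAsFactors = FALSE)
      next
    }
    win <- pc[pc$sign == sign(net), , drop = FALSE]
    rows[[i]] <- data.frame(gene = pc$accession[1], earlier = pc$earlier[1],
                            later = pc$later[1], pair = pc$pair[1],
                            sign = sign(net), pair_p = min(win$pair_p),
                            fold_change = 2^mean(log2(win$fold_change)),
                            n_probes = nrow(win), stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(out$gene, out$pair), , drop = FALSE]
  rownames(out) <- NULL
  tie_df <- if (length(ties)) do.call(rbind, ties) else empty[0, c("gene", "pair")]
  if (nrow(tie_df))
    message(nrow(tie_df), " (gene, pair) direction tie(s) dropped")
  attr(out, "ties") <- tie_df
  out
}
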