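#' Expression matrix with per-spot presence mask
#'
#' Container for single-channel microarray intensities: a probes x samples
#' matrix of strictly positive linear-scale values plus a logical mask of
#' the same shape recording which spots survived flagging ("present").
#' All statistical stages of the package consume this object; statistics
#' are computed on log2 of the present intensities.
#'
#' @param intensities numeric matrix, probes in rows, samples in columns;
#'   dimnames are required and become the probe and sample identifiers.
#'   Values must be positive wherever the spot is present.
#' @param presence logical matrix of the same dimension, `TRUE` where the
#'   spot is present. Defaults to all-present.
#' @return An object of class `expr_matrix`: a list with elements
#'   `intensities` and `presence`.
#' @examples
#' m <- matrix(2^rnorm(12, 8), 4, 3,
#'             dimnames = list(paste0("p", 1:4), paste0("s", 1:3)))
#' x <- expression_matrix(m)
#' dim(x)
#' @export
expression_matrix <- function(intensities, presence = NULL) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("'intensities' must be a numeric matrix")
  if ((nrow(intensities) > 0 && is.null(rownames(intensities))) ||
      (ncol(intensities) > 0 && is.null(colnames(intensities))))
    stop("'intensities' must carry probe (row) and sample (column) names")
  if (nrow(intensities) == 0) rownames(intensities) <- character(0)
  if (ncol(intensities) == 0) colnames(intensities) <- character(0)
  if (anyDuplicated(rownames(intensities)))
    stop("duplicated probe ids")
  if (anyDuplicated(colnames(intensities)))
    stop("duplicated sample ids")
  if (is.null(presence)) {
    presence <- matrix(TRUE, nrow(intensities), ncol(intensities),
                       dimnames = dimnames(intensities))
  }
  if (!is.matrix(presence) || !is.logical(presence) ||
      !identical(dim(presence), dim(intensities)))
    stop("'presence' must be a logical matrix matching 'intensities'")
  dimnames(presence) <- dimnames(intensities)
  bad <- presence & !(is.finite(intensities) & intensities > 0)
  if (any(bad))
    stop(sum(bad), " present spot(s) have non-positive or non-finite intensity")
  structure(list(intensities = intensities, presence = presence),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$intensities)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$intensities)

#' Subset an expression matrix
#'
#' Row (probe) and column (sample) subsetting; both matrix slots are
#' subset together and dimensions are always kept.
#'
#' @param x an `expr_matrix`.
#' @param i,j probe / sample indices (any form `[` accepts).
#' @param ... ignored.
#' @return An `expr_matrix`.
#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$intensities))
  if (missing(j)) j <- seq_len(ncol(x$intensities))
  expression_matrix(x$intensities[i, j, drop = FALSE],
                    x$presence[i, j, drop = FALSE])
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes x %d samples (%.1f%% spots present)\n",
              nrow(x$intensities), ncol(x$intensities),
              100 * mean(x$presence)))
  invisible(x)
}

#' @export
summary.expr_matrix <- function(object, ...) {
  v <- object$intensities[object$presence]
  cat(sprintf("expr_matrix: %d probes x %d samples\n",
              nrow(object$intensities), ncol(object$intensities)))
  cat(sprintf("present spots: %d (%.1f%%), intensity range [%.3g, %.3g]\n",
              sum(object$presence), 100 * mean(object$presence),
              min(v), max(v)))
  invisible(object)
}

# Log2 intensities with absent spots set NA; internal working form.
log2_present <- function(x) {
  m <- log2(x$intensities)
  m[!x$presence] <- NA_real_
  m
}

#' Validate a design table against an expression matrix
#'
#' The design assigns every sample of the matrix to one stage of the
#' NC1 -> C1 -> C2 competence series. Used internally by every stage-aware
#' operation; exported because pipeline inputs are user-supplied.
#'
#' @param design data.frame with columns `sample`, `stage` (values among
#'   `NC1`, `C1`, `C2`), and optionally `species`, `replicate`.
#' @param x an `expr_matrix` whose samples the design must cover exactly.
#' @return The design with `stage` as a factor levelled `NC1, C1, C2`,
#'   ordered to match the matrix columns.
#' @export
validate_design <- function(design, x) {
  if (!is.data.frame(design) || !all(c("sample", "stage") %in% names(design)))
    stop("'design' needs columns 'sample' and 'stage'")
  design$sample <- as.character(design$sample)
  design$stage <- as.character(design$stage)
  if (anyDuplicated(design$sample))
    stop("duplicated sample ids in design")
  bad_stage <- setdiff(unique(design$stage), STAGES)
  if (length(bad_stage))
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "))
  samples <- colnames(x$intensities)
  unknown <- setdiff(design$sample, samples)
  if (length(unknown))
    stop("design samples not in matrix: ", paste(unknown, collapse = ", "))
  missing <- setdiff(samples, design$sample)
  if (length(missing))
    stop("matrix samples not in design: ", paste(missing, collapse = ", "))
  design <- design[match(samples, design$sample), , drop = FALSE]
  design$stage <- factor(design$stage, levels = STAGES)
  rownames(design) <- NULL
  design
}

# Stage labels of the competence series, in developmental order.
STAGES <- c("NC1", "C1", "C2")

# The three ordered stage contrasts (earlier, later) used for direction calls.
STAGE_PAIRS <- list(c("NC1", "C1"), c("C1", "C2"), c("NC1", "C2"))

pair_label <- function(earlier, later) paste(earlier, later, sep = ":")
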