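#' Read / write the package's plain-text interchange formats
#'
#' Expression matrices travel as TSV (probes in rows, samples in columns;
#' presence as an optional parallel TSV of 0/1), designs as CSV, similarity
#' as 12-column BLAST `outfmt 6`, annotation as GMT, ortholog groups in the
#' OrthoMCL `groups.txt` dialect.
#'
#' @param path file path.
#' @param presence_path optional path of a parallel 0/1 presence TSV.
#' @return `read_expression_tsv`: an [expression_matrix()].
#' @name io
NULL

#' @rdname io
#' @export
read_expression_tsv <- function(path, presence_path = NULL) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  pres <- NULL
  if (!is.null(presence_path)) {
    p <- as.matrix(utils::read.table(presence_path, header = TRUE, sep = "\t",
                                     row.names = 1, check.names = FALSE))
    pres <- p[rownames(m), colnames(m), drop = FALSE] != 0
  }
  expression_matrix(m, pres)
}

#' @rdname io
#' @param x object to write.
#' @export
write_expression_tsv <- function(x, path, presence_path = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(probe = rownames(x$intensities), x$intensities,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(presence_path)) {
    dfp <- data.frame(probe = rownames(x$presence), x$presence * 1L,
                      check.names = FALSE)
    utils::write.table(dfp, presence_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname io
#' @export
read_design_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname io
#' @param design design data.frame.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @details `read_blast_outfmt6` expects the standard 12 columns
#'   (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#'   evalue bitscore). When sequence ids follow the `species|gene`
#'   convention the result can be converted to the package's similarity
#'   table with [as_similarity()].
#' @export
read_blast_outfmt6 <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) != 12L)
    stop("expected 12 tab-separated columns (BLAST outfmt 6), got ", ncol(df))
  names(df) <- cols
  df
}

#' @rdname io
#' @param records similarity table (see [as_similarity()]).
#' @export
write_blast_outfmt6 <- function(records, path) {
  records <- as_similarity(records)
  df <- data.frame(
    qseqid = paste(records$qspecies, records$qgene, sep = "|"),
    sseqid = paste(records$sspecies, records$sgene, sep = "|"),
    pident = 100, length = 100L, mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
    evalue = records$evalue, bitscore = records$bitscore)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Coerce a hit table to the internal similarity form
#'
#' The internal similarity table has columns `qspecies`, `qgene`,
#' `sspecies`, `sgene`, `evalue`, `bitscore`. BLAST outfmt-6 frames (as
#' from [read_blast_outfmt6()]) are accepted when their `qseqid`/`sseqid`
#' use the `species|gene` convention of OrthoMCL compliant FASTA headers.
#'
#' @param records a similarity table in either form.
#' @return data.frame in the internal six-column form.
#' @export
as_similarity <- function(records) {
  need <- c("qspecies", "qgene", "sspecies", "sgene", "evalue", "bitscore")
  if (all(need %in% names(records)))
    return(records[need])
  if (all(c("qseqid", "sseqid", "evalue", "bitscore") %in% names(records))) {
    qs <- split_taxon_id(records$qseqid)
    ss <- split_taxon_id(records$sseqid)
    return(data.frame(qspecies = qs$species, qgene = qs$gene,
                      sspecies = ss$species, sgene = ss$gene,
                      evalue = records$evalue, bitscore = records$bitscore,
                      stringsAsFactors = FALSE))
  }
  stop("cannot interpret 'records' as a similarity table")
}

split_taxon_id <- function(id) {
  bad <- !grepl("|", id, fixed = TRUE)
  if (any(bad))
    stop("sequence id(s) not in 'species|gene' form: ",
         paste(utils::head(id[bad], 3), collapse = ", "))
  sp <- sub("\\|.*$", "", id)
  g <- sub("^[^|]*\\|", "", id)
  list(species = sp, gene = g)
}

#' @rdname io
#' @details GMT lines are `term<TAB>description<TAB>gene1<TAB>gene2...`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT line (need term, description, >=1 gene): ", ln)
    out[[parts[1]]] <- unique(parts[-(1:2)])
  }
  out
}

#' @rdname io
#' @param annotation named list, term id -> character vector of genes.
#' @export
write_gmt <- function(annotation, path) {
  lines <- vapply(names(annotation), function(tm) {
    paste(c(tm, tm, annotation[[tm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
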