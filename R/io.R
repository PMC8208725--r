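#' @importFrom GenomicRanges GRanges findOverlaps reduce distance
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom methods is
#' @importFrom stats median p.adjust pnorm rbinom rgamma rnbinom rnorm rpois
#'   runif setNames wilcox.test fisher.test cor t.test quantile sd complete.cases
#' @importFrom utils read.delim write.table head modifyList
NULL

# All internal coordinates are 0-based half-open (BED native). 1-based inputs
# (VCF-like) are shifted at the I/O boundary and nowhere else.

.sw_header <- function(cfg = NULL) {
  ver <- as.character(utils::packageVersion("strainwise"))
  hash <- if (is.null(cfg)) "none" else config_hash(cfg)
  sprintf("# strainwise %s config=%s", ver, hash)
}

.read_table_skip_comments <- function(path, col.names, colClasses = NA) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  if (!any(keep))
    return(stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(col.names))),
                           col.names))
  read.delim(text = lines[keep], header = FALSE, col.names = col.names,
             colClasses = colClasses, stringsAsFactors = FALSE)
}

#' Read genomic intervals from a BED file
#'
#' BED coordinates are 0-based half-open and are preserved exactly. Element
#' ids come from column 4 when present, otherwise generated as
#' `chrom:start-end`.
#'
#' @param path BED3+ file path.
#' @return data.frame with columns `chrom`, `start`, `end`, `id`, `kind`
#'   (kind defaults to `"unassigned"`; column 5, when present and one of
#'   `promoter`/`enhancer`, is used as kind).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      id = character(), kind = character(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3L))
    stop("BED line ", which(ncols < 3L)[1L], ": fewer than 3 columns", call. = FALSE)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end   <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("BED line ", bad[1L], ": non-numeric coordinates", call. = FALSE)
  bad <- which(start >= end)
  if (length(bad))
    stop("BED line ", bad[1L], ": start must be smaller than end", call. = FALSE)
  id <- ifelse(ncols >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""),
               sprintf("%s:%d-%d", chrom, start, end))
  kind <- rep("unassigned", length(lines))
  has5 <- ncols >= 5L
  k5 <- vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else "", "")
  kind[has5 & k5 %in% c("promoter", "enhancer")] <- k5[has5 & k5 %in% c("promoter", "enhancer")]
  if (anyDuplicated(id))
    stop("duplicate element id in BED: ", id[duplicated(id)][1L], call. = FALSE)
  data.frame(chrom = chrom, start = start, end = end, id = id, kind = kind,
             stringsAsFactors = FALSE)
}

#' Write genomic intervals as BED
#' @param intervals data.frame as returned by [read_bed()].
#' @param path output path.
#' @param cfg optional configuration, stamped into the header comment.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, cfg = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.sw_header(cfg), con)
  if (nrow(intervals)) {
    kind <- if ("kind" %in% names(intervals)) intervals$kind else "unassigned"
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s", intervals$chrom,
                       as.integer(intervals$start), as.integer(intervals$end),
                       intervals$id, kind), con)
  }
  invisible(path)
}

#' Read / write a signal table
#'
#' A signal table holds normalized tag counts (tags per 1e7) keyed by
#' (element id, strain, condition, assay). Duplicate keys and negative values
#' are rejected.
#'
#' @param path TSV path with header columns
#'   `element_id, strain, condition, assay, value`.
#' @return data.frame with those columns.
#' @export
read_signal_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  tab <- read.delim(text = lines, header = TRUE, stringsAsFactors = FALSE)
  need <- c("element_id", "strain", "condition", "assay", "value")
  if (!all(need %in% names(tab)))
    stop("signal table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tab <- tab[, need]
  tab$value <- as.numeric(tab$value)
  if (any(is.na(tab$value)))
    stop("signal table contains non-numeric values", call. = FALSE)
  if (any(tab$value < 0))
    stop("signal table contains negative values", call. = FALSE)
  key <- paste(tab$element_id, tab$strain, tab$condition, tab$assay, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate signal key: ", gsub("\r", "/", d, fixed = TRUE), call. = FALSE)
  }
  tab
}

#' @rdname read_signal_table
#' @param table signal table data.frame.
#' @param cfg optional configuration stamped into the header comment.
#' @export
write_signal_table <- function(table, path, cfg = NULL) {
  stopifnot(all(c("element_id", "strain", "condition", "assay", "value") %in% names(table)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.sw_header(cfg), con)
  write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an expression table
#'
#' Rows are keyed by (gene id, strain, condition, replicate) and carry TPM and
#' raw counts; `q` (adjusted p-value of the induction contrast per gene and
#' strain) is optional and may be NA.
#'
#' @param path TSV with header
#'   `gene_id, strain, condition, replicate, tpm, count[, q]`.
#' @return data.frame.
#' @export
read_expression_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  tab <- read.delim(text = lines, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "strain", "condition", "replicate", "tpm", "count")
  if (!all(need %in% names(tab)))
    stop("expression table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"q" %in% names(tab)) tab$q <- NA_real_
  if (any(tab$tpm < 0, na.rm = TRUE)) stop("negative TPM", call. = FALSE)
  if (any(tab$count < 0 | tab$count != round(tab$count), na.rm = TRUE))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(!is.na(tab$q) & (tab$q < 0 | tab$q > 1)))
    stop("q values must lie in [0, 1]", call. = FALSE)
  tab
}

#' @rdname read_expression_table
#' @param table expression table data.frame.
#' @param cfg optional configuration stamped into the header comment.
#' @export
write_expression_table <- function(table, path, cfg = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.sw_header(cfg), con)
  write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a minimal VCF-like variant table
#'
#' Expects a TSV with columns `chrom, pos, ref, alt, strain` where `pos` is
#' 1-based (VCF convention). Positions are shifted to the package-internal
#' 0-based convention at read time; [write_vcf_like()] shifts back, so the
#' files round-trip.
#'
#' @param path variant TSV path.
#' @return data.frame with columns `chrom, pos` (0-based), `ref, alt, strain`.
#' @export
read_vcf_like <- function(path) {
  tab <- .read_table_skip_comments(path, c("chrom", "pos", "ref", "alt", "strain"),
                                   colClasses = c("character", "integer",
                                                  "character", "character",
                                                  "character"))
  if (nrow(tab)) {
    if (any(is.na(tab$pos))) stop("non-numeric variant position", call. = FALSE)
    if (any(!nzchar(tab$ref) | !nzchar(tab$alt)))
      stop("variant alleles must be non-empty", call. = FALSE)
    if (any(tab$ref == tab$alt))
      stop("ref and alt alleles must differ", call. = FALSE)
    tab$pos <- tab$pos - 1L
    tab$ref <- toupper(tab$ref)
    tab$alt <- toupper(tab$alt)
  }
  tab
}

#' @rdname read_vcf_like
#' @param variants variant data.frame (0-based `pos`).
#' @param cfg optional configuration stamped into the header comment.
#' @export
write_vcf_like <- function(variants, path, cfg = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.sw_header(cfg), con)
  writeLines("#chrom\tpos\tref\talt\tstrain", con)
  if (nrow(variants))
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s", variants$chrom,
                       as.integer(variants$pos) + 1L, variants$ref,
                       variants$alt, variants$strain), con)
  invisible(path)
}

#' Read interaction pairs from a BEDPE file
#'
#' @param path BEDPE path (6 coordinate columns; column 7 is an optional name,
#'   column 8 an optional read-pair count used as interaction strength).
#' @return data.frame with columns `chrom1, start1, end1, chrom2, start2,
#'   end2, strength`.
#' @export
read_bedpe <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom1 = character(), start1 = integer(), end1 = integer(),
                      chrom2 = character(), start2 = integer(), end2 = integer(),
                      strength = numeric(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 6L))
    stop("BEDPE line ", which(lengths(fields) < 6L)[1L],
         ": fewer than 6 columns", call. = FALSE)
  num <- function(i) suppressWarnings(as.integer(vapply(fields, `[[`, "", i)))
  out <- data.frame(
    chrom1 = vapply(fields, `[[`, "", 1L), start1 = num(2L), end1 = num(3L),
    chrom2 = vapply(fields, `[[`, "", 4L), start2 = num(5L), end2 = num(6L),
    stringsAsFactors = FALSE)
  if (any(is.na(out$start1) | is.na(out$end1) | is.na(out$start2) | is.na(out$end2)))
    stop("non-numeric BEDPE coordinates", call. = FALSE)
  out$strength <- vapply(fields, function(f)
    if (length(f) >= 8L) suppressWarnings(as.numeric(f[[8L]])) else 1, 1)
  out$strength[is.na(out$strength)] <- 1
  if (any(out$strength < 0)) stop("negative interaction strength", call. = FALSE)
  out
}

#' @rdname read_bedpe
#' @param interactions interaction data.frame.
#' @param cfg optional configuration stamped into the header comment.
#' @export
write_bedpe <- function(interactions, path, cfg = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.sw_header(cfg), con)
  if (nrow(interactions))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%d\t.\t%g",
                       interactions$chrom1, as.integer(interactions$start1),
                       as.integer(interactions$end1), interactions$chrom2,
                       as.integer(interactions$start2), as.integer(interactions$end2),
                       interactions$strength), con)
  invisible(path)
}

#' Read / write genome sequences (FASTA)
#'
#' Sequences are upper-cased on read. Returns a named character vector, the
#' package-internal sequence representation.
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
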