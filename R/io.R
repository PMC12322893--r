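#' Table readers and writers
#'
#' chromlink works with three plain-TSV table kinds, all held as data.frames
#' in internal 0-based half-open coordinates:
#'
#' * gene tables: `chrom, start, end, gene_id, gene_name, strand, source_tag`
#' * peak tables: `chrom, start, end, mark, sign, peak_id, lncrna_id,
#'   associated_gene`
#' * contact tables: `chrom, start, end, lncrna_id, experiment_id`
#'
#' Readers accept files with or without a header line (auto-detected: if the
#' coordinate fields of the first line do not parse as integers it is taken
#' as a header). Writers always emit a header. Readers are faithful:
#' duplicate rows are kept and row order is preserved.
#'
#' @name chromlink-io
NULL

#' Default histone-mark vocabulary
#'
#' The ten chromatin marks accepted by [read_peak_table()] and the synthetic
#' generator. Eight are the marks that recur throughout lncRNA-correlated
#' peak catalogues (H3K27ac, H3K27me3, H3K36me3, H3K4me1, H3K4me2, H3K4me3,
#' H3K79me2, H3K9me3); H3K9ac and H4K20me1 fill the remaining two slots of
#' the usual ten-mark ChIP-seq panel and can be replaced freely.
#'
#' @return character vector of 10 mark labels.
#' @export
himorna_marks <- function() {
  c("H3K27ac", "H3K27me3", "H3K36me3", "H3K4me1", "H3K4me2",
    "H3K4me3", "H3K79me2", "H3K9me3", "H3K9ac", "H4K20me1")
}

.read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(lines)]
}

.split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

.is_int <- function(x) grepl("^[0-9]+$", x)

# TRUE when the first data line looks like a header (coordinate columns
# at positions 2 and 3 are not integers)
.has_header <- function(fields) {
  f <- fields[[1L]]
  length(f) >= 3L && !(.is_int(f[2L]) && .is_int(f[3L]))
}

.coord_cols <- function(fields, lineno, path) {
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("%s: coordinate parse failure at line %d", path, lineno[bad[1L]]),
         call. = FALSE)
  list(start = start, end = end)
}

.check_ncol <- function(fields, minimum, lineno, path) {
  bad <- which(vapply(fields, length, 1L) < minimum)
  if (length(bad))
    stop(sprintf("%s: missing mandatory column at line %d (expected >= %d fields)",
                 path, lineno[bad[1L]], minimum), call. = FALSE)
}

# normalise the sign column: unicode minus and hyphen both mean "-"
.norm_sign <- function(sign, lineno, path) {
  sign <- ifelse(sign == "−", "-", sign)
  bad <- which(!sign %in% c("+", "-"))
  if (length(bad))
    stop(sprintf("%s: invalid sign %s at line %d (must be '+' or '-')",
                 path, sQuote(sign[bad[1L]]), lineno[bad[1L]]), call. = FALSE)
  sign
}

#' Read a gene annotation table
#'
#' @param path TSV file path.
#' @param dialect `"bed_tsv"` (columns `chrom, start, end, gene_id,
#'   gene_name, strand`; coordinates taken 0-based half-open as-is) or
#'   `"gtf_lite"` (9-column GTF whose `gene` rows are used; 1-based
#'   inclusive coordinates are converted; `gene_id`/`gene_name` parsed from
#'   the attributes column).
#' @param source_tag label recorded in the `source_tag` column ("A"/"B").
#' @return data.frame of gene records in file order.
#' @export
read_gene_table <- function(path, dialect = c("bed_tsv", "gtf_lite"),
                            source_tag = "A") {
  dialect <- match.arg(dialect)
  lines <- .read_tsv_lines(path)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      gene_id = character(), gene_name = character(),
                      strand = character(), source_tag = character(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- .split_fields(lines)
  lineno <- seq_along(lines)

  if (dialect == "gtf_lite") {
    keep <- vapply(fields, function(f) length(f) >= 9L && f[3L] == "gene",
                   logical(1L))
    fields <- fields[keep]; lineno <- lineno[keep]
    if (!length(fields)) return(empty)
    start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad))
      stop(sprintf("%s: coordinate parse failure at line %d", path, lineno[bad[1L]]),
           call. = FALSE)
    attrs <- vapply(fields, `[`, "", 9L)
    get_attr <- function(key) {
      pat <- paste0(key, '[ =]+"?([^";]+)"?')
      hit <- regexpr(pat, attrs, perl = TRUE)
      out <- rep(NA_character_, length(attrs))
      got <- hit > 0
      raw <- regmatches(attrs, hit)
      val <- sub(paste0("^", key, '[ =]+"?'), "", raw)
      out[got] <- sub('"$', "", val)
      out
    }
    gene_id <- get_attr("gene_id")
    gene_name <- get_attr("gene_name")
    if (anyNA(gene_id))
      stop(sprintf("%s: missing gene_id attribute at line %d",
                   path, lineno[which(is.na(gene_id))[1L]]), call. = FALSE)
    gene_name[is.na(gene_name)] <- gene_id[is.na(gene_name)]
    return(data.frame(
      chrom = vapply(fields, `[`, "", 1L),
      start = start - 1, end = end,
      gene_id = gene_id, gene_name = gene_name,
      strand = vapply(fields, `[`, "", 7L),
      source_tag = source_tag, stringsAsFactors = FALSE))
  }

  if (.has_header(fields)) { fields <- fields[-1L]; lineno <- lineno[-1L] }
  if (!length(fields)) return(empty)
  .check_ncol(fields, 5L, lineno, path)
  cc <- .coord_cols(fields, lineno, path)
  strand <- vapply(fields, function(f) if (length(f) >= 6L) f[6L] else ".", "")
  strand[!strand %in% c("+", "-", ".")] <- "."
  data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    start = cc$start, end = cc$end,
    gene_id = vapply(fields, `[`, "", 4L),
    gene_name = vapply(fields, `[`, "", 5L),
    strand = strand, source_tag = source_tag, stringsAsFactors = FALSE)
}

#' Read a peak table
#'
#' Columns: `chrom, start, end, mark, sign, peak_id, lncrna_id` and an
#' optional eighth `associated_gene`. Coordinates are 0-based half-open.
#' The sign must be `"+"` or `"-"` (a unicode minus is accepted and
#' normalised); the mark must belong to `marks`.
#'
#' @param path TSV file path.
#' @param marks allowed histone-mark vocabulary.
#' @return data.frame of peaks in file order (duplicates kept).
#' @export
read_peak_table <- function(path, marks = himorna_marks()) {
  lines <- .read_tsv_lines(path)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      mark = character(), sign = character(),
                      peak_id = character(), lncrna_id = character(),
                      associated_gene = character(), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- .split_fields(lines)
  lineno <- seq_along(lines)
  if (.has_header(fields)) { fields <- fields[-1L]; lineno <- lineno[-1L] }
  if (!length(fields)) return(empty)
  .check_ncol(fields, 7L, lineno, path)
  cc <- .coord_cols(fields, lineno, path)
  mark <- vapply(fields, `[`, "", 4L)
  bad <- which(!mark %in% marks)
  if (length(bad))
    stop(sprintf("%s: unknown histone mark %s at line %d",
                 path, sQuote(mark[bad[1L]]), lineno[bad[1L]]), call. = FALSE)
  sign <- .norm_sign(vapply(fields, `[`, "", 5L), lineno, path)
  gene <- vapply(fields, function(f) if (length(f) >= 8L) f[8L] else NA_character_, "")
  gene[gene == "NA"] <- NA_character_
  data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    start = cc$start, end = cc$end, mark = mark, sign = sign,
    peak_id = vapply(fields, `[`, "", 6L),
    lncrna_id = vapply(fields, `[`, "", 7L),
    associated_gene = gene, stringsAsFactors = FALSE)
}

#' Read a contact table
#'
#' Columns: `chrom, start, end, lncrna_id, experiment_id`; 0-based
#' half-open coordinates.
#'
#' @param path TSV file path.
#' @return data.frame of contacts in file order (duplicates kept).
#' @export
read_contact_table <- function(path) {
  lines <- .read_tsv_lines(path)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      lncrna_id = character(), experiment_id = character(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- .split_fields(lines)
  lineno <- seq_along(lines)
  if (.has_header(fields)) { fields <- fields[-1L]; lineno <- lineno[-1L] }
  if (!length(fields)) return(empty)
  .check_ncol(fields, 5L, lineno, path)
  cc <- .coord_cols(fields, lineno, path)
  data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    start = cc$start, end = cc$end,
    lncrna_id = vapply(fields, `[`, "", 4L),
    experiment_id = vapply(fields, `[`, "", 5L),
    stringsAsFactors = FALSE)
}

#' Write chromlink tables as TSV
#'
#' Emit a gene, peak or contact table (or any result data.frame) with a
#' header line; round-trips exactly through the matching reader.
#'
#' @param x data.frame to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Strip the version suffix from a gene identifier
#'
#' `"ENSG00000267034.1"` becomes `"ENSG00000267034"`; identifiers without a
#' dot are returned unchanged. Used for version-insensitive ID matching
#' across annotation releases.
#'
#' @param gene_id character vector of (possibly versioned) identifiers.
#' @return character vector of unversioned identifiers.
#' @export
strip_gene_version <- function(gene_id) {
  sub("\\.[^.]*$", "", gene_id)
}
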