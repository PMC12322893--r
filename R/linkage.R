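#' Cross-database navigation URLs
#'
#' The integrated web interfaces let a user jump from a peak catalogue entry
#' to the RNA-chromatin contact browser via URLs of the form
#' `<base>basic_graphical_summary_dna_filter?locus=...&name=...&rnaID=...&organism=...`.
#' [build_rnachrom_url()] renders these for the three navigation modes and
#' optionally widens the locus first; [parse_rnachrom_url()] inverts it.
#'
#' @name linkage
NULL

.RNACHROM_BASE <- "https://rnachrom2.bioinf.fbb.msu.ru/"
.RNACHROM_ENDPOINT <- "basic_graphical_summary_dna_filter"

#' Allowed locus-extension menu choices (bases)
#' @return integer vector: 1, 5, 10, 25, 50 and 100 kb.
#' @export
extension_choices <- function() c(1000L, 5000L, 10000L, 25000L, 50000L, 100000L)

#' Build an RNA-chromatin browser URL
#'
#' Parameter order is fixed: `locus`, `name`, `rnaID`, `organism`. The locus
#' is rendered in 1-based display coordinates (so an extension clamped at
#' the chromosome start shows position 1); spaces in the organism are
#' encoded as `+`, matching the target site's own links rather than
#' percent-encoding.
#'
#' @param lncrna_name RNA name shown to the user (e.g. `"XIST"`).
#' @param rna_id the contact database's internal numeric RNA identifier.
#' @param organism organism name, e.g. `"Homo sapiens"`.
#' @param locus optional interval (data.frame from [parse_locus()] /
#'   [genomic_interval()], or a locus string). Required for modes that
#'   restrict to a locus.
#' @param extend optional extension in bases applied to the locus before
#'   rendering; one of [extension_choices()] (or 0/NULL for none).
#' @param mode `"locus_contacts"` (contacts of the RNA in the locus;
#'   requires `locus`), `"all_contacts"` (all contacts of the RNA; no locus
#'   parameter), or `"all_rnas_at_locus"` (all RNAs contacting the locus;
#'   requires `locus`, no `name`/`rnaID`). Only the first mode's URL shape
#'   is documented by the target site; the other two reuse its parameter
#'   vocabulary.
#' @param base base URL of the contact database.
#' @return URL string.
#' @examples
#' build_rnachrom_url("XIST", 227896, "Homo sapiens",
#'                    locus = "chrX:23456-24253566")
#' @export
build_rnachrom_url <- function(lncrna_name = NULL, rna_id = NULL,
                               organism = "Homo sapiens", locus = NULL,
                               extend = NULL,
                               mode = c("locus_contacts", "all_contacts",
                                        "all_rnas_at_locus"),
                               base = .RNACHROM_BASE) {
  mode <- match.arg(mode)
  if (is.character(locus) && length(locus) == 1L) locus <- parse_locus(locus)
  need <- function(what, val) {
    if (is.null(val) || (is.character(val) && !nzchar(val)))
      stop("missing required field for mode ", sQuote(mode), ": ", what,
           call. = FALSE)
  }
  if (mode %in% c("locus_contacts", "all_rnas_at_locus")) need("locus", locus)
  if (mode %in% c("locus_contacts", "all_contacts")) {
    need("lncrna_name", lncrna_name); need("rna_id", rna_id)
  }
  need("organism", organism)
  if (!is.null(extend) && !is.null(locus) && extend > 0) {
    if (!extend %in% extension_choices())
      stop("extend must be one of ", paste(extension_choices(), collapse = ", "),
           call. = FALSE)
    locus <- extend_interval(locus, extend)
  }
  params <- character()
  if (!is.null(locus) && mode != "all_contacts")
    params <- c(params, paste0("locus=", format_locus(locus)))
  if (mode != "all_rnas_at_locus")
    params <- c(params,
                paste0("name=", lncrna_name),
                paste0("rnaID=", rna_id))
  params <- c(params, paste0("organism=", gsub(" ", "+", organism, fixed = TRUE)))
  paste0(base, .RNACHROM_ENDPOINT, "?", paste(params, collapse = "&"))
}

#' Parse an RNA-chromatin browser URL back into its query fields
#'
#' Inverse of [build_rnachrom_url()] for round-trip checks.
#'
#' @param url URL string produced by [build_rnachrom_url()].
#' @return list with `locus` (data.frame or NULL), `lncrna_name`, `rna_id`,
#'   `organism`, `mode`.
#' @export
parse_rnachrom_url <- function(url) {
  q <- sub("^[^?]*\\?", "", url)
  kv <- strsplit(strsplit(q, "&", fixed = TRUE)[[1L]], "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  locus <- if ("locus" %in% names(vals)) parse_locus(vals[["locus"]]) else NULL
  name <- if ("name" %in% names(vals)) vals[["name"]] else NULL
  mode <- if (is.null(locus)) "all_contacts"
          else if (is.null(name)) "all_rnas_at_locus"
          else "locus_contacts"
  list(locus = locus,
       lncrna_name = name,
       rna_id = if ("rnaID" %in% names(vals)) vals[["rnaID"]] else NULL,
       organism = gsub("+", " ", vals[["organism"]], fixed = TRUE),
       mode = mode)
}
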