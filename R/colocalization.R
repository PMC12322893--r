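#' Peak confirmation by window-extended contacts
#'
#' A peak is "confirmed" (supported) when at least one RNA-chromatin contact
#' of the same lncRNA, extended by +/- w bases, shares at least one base
#' with it on the same chromosome. Contacts of other lncRNAs never confirm,
#' whatever the geometry. In half-open arithmetic, extension by w is
#' equivalent to allowing a genomic gap of at most w - 1 between peak and
#' raw contact (or an overlap); mere adjacency at w = 0 does not confirm.
#'
#' @name colocalization
NULL

#' Default contact-extension windows
#'
#' 0 plus 1, 5, 10, 25 and 50 kb, in bases.
#' @return integer vector of window widths.
#' @export
default_windows <- function() c(0L, 1000L, 5000L, 10000L, 25000L, 50000L)

#' Confirm peaks by extended contacts of the same lncRNA
#'
#' @param peaks peak table ([read_peak_table()] columns).
#' @param contacts contact table ([read_contact_table()] columns).
#' @param w extension window in bases (applied to the contacts).
#' @return logical vector, one element per peak row, `TRUE` when the peak
#'   overlaps (>= 1 base) some w-extended contact of its lncRNA. Independent
#'   of input row order.
#' @export
confirm_peaks <- function(peaks, contacts, w = 0) {
  stopifnot(w >= 0)
  if (nrow(peaks) == 0L) return(logical(0))
  if (nrow(contacts) == 0L) return(rep(FALSE, nrow(peaks)))
  ext <- extend_interval(contacts[, c("chrom", "start", "end")], w)
  # composite seqnames make findOverlaps respect lncRNA attribution
  gp <- .as_granges(paste0(peaks$lncrna_id, "\r", peaks$chrom),
                    peaks$start, peaks$end)
  gc <- .as_granges(paste0(contacts$lncrna_id, "\r", ext$chrom),
                    ext$start, ext$end)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gp, gc, minoverlap = 1L, ignore.strand = TRUE))
  out <- rep(FALSE, nrow(peaks))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

#' Confirmation proportions per lncRNA across extension windows
#'
#' @param peaks,contacts as in [confirm_peaks()].
#' @param windows vector of extension widths in bases
#'   (default [default_windows()]).
#' @param lncrnas lncRNA identifiers to report (default: all lncRNAs present
#'   in `peaks`); an lncRNA with no peaks yields `n_peaks = 0` and an `NA`
#'   proportion, flagged in `no_peaks`.
#' @return data.frame with one row per (lncRNA, window): `lncrna_id`,
#'   `window`, `n_peaks`, `n_confirmed`, `proportion`, `no_peaks`. For a
#'   fixed lncRNA the proportion is non-decreasing in the window.
#' @export
confirmation_sweep <- function(peaks, contacts, windows = default_windows(),
                               lncrnas = NULL) {
  if (is.null(lncrnas)) lncrnas <- sort(unique(peaks$lncrna_id))
  windows <- sort(unique(as.numeric(windows)))
  out <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    conf <- confirm_peaks(peaks, contacts, windows[i])
    n_peaks <- vapply(lncrnas, function(l) sum(peaks$lncrna_id == l), 1L)
    n_conf <- vapply(lncrnas, function(l) sum(conf[peaks$lncrna_id == l]), 1L)
    out[[i]] <- data.frame(
      lncrna_id = lncrnas, window = windows[i],
      n_peaks = n_peaks, n_confirmed = n_conf,
      proportion = ifelse(n_peaks > 0, n_conf / n_peaks, NA_real_),
      no_peaks = n_peaks == 0L,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

#' lncRNA-level confirmation summary at one window
#'
#' Counts, over the lncRNAs carrying peaks, how many have at least one
#' contact anywhere in the contact table and how many have at least one
#' confirmed peak at window `w`; the confirmed fraction is taken over the
#' lncRNAs that have contacts.
#'
#' @param peaks,contacts,w as in [confirm_peaks()].
#' @param lncrnas lncRNA universe (default: those present in `peaks`).
#' @return list with `n_lncrnas`, `n_with_any_contact`,
#'   `n_with_confirmed_peak`, `fraction_confirmed` (NA, flagged by
#'   `undefined = TRUE`, when no lncRNA has contacts).
#' @export
lncrna_level_summary <- function(peaks, contacts, w = 0, lncrnas = NULL) {
  if (is.null(lncrnas)) lncrnas <- sort(unique(peaks$lncrna_id))
  has_contact <- lncrnas %in% unique(contacts$lncrna_id)
  conf <- confirm_peaks(peaks, contacts, w)
  confirmed_lnc <- unique(peaks$lncrna_id[conf])
  has_confirmed <- lncrnas %in% confirmed_lnc
  n_any <- sum(has_contact)
  n_conf <- sum(has_confirmed)
  list(n_lncrnas = length(lncrnas),
       n_with_any_contact = n_any,
       n_with_confirmed_peak = n_conf,
       fraction_confirmed = if (n_any > 0) n_conf / n_any else NA_real_,
       undefined = n_any == 0L)
}
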