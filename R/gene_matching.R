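#' Cross-version gene annotation reconciliation
#'
#' Two gene annotations (e.g. GENCODE v31 vs v35) rarely agree on
#' identifiers or exact coordinates. chromlink reconciles them in three
#' steps: [overlap_pairs()] enumerates every same-chromosome coordinate
#' overlap and scores three similarity metrics (gene-name equality,
#' version-insensitive gene-ID equality, Jaccard index of the intervals);
#' [classify_groups()] bins pairs by which metrics they satisfy; and
#' [resolve_one_to_one()] turns the pairs into a one-to-one correspondence
#' table, using Jaccard index > threshold as the primary criterion and a
#' unique gene-name match as the fallback.
#'
#' @name gene-matching
NULL

#' Matching configuration
#'
#' @param jaccard_threshold minimum Jaccard index for a coordinate-based
#'   match (default 0.99; a pair qualifies when its index is strictly
#'   greater).
#' @param version_insensitive_id strip `.N` version suffixes before
#'   comparing gene IDs (default `TRUE`; across annotation releases the
#'   version almost always differs).
#' @return list of class `match_config`.
#' @export
match_config <- function(jaccard_threshold = 0.99, version_insensitive_id = TRUE) {
  stopifnot(jaccard_threshold > 0, jaccard_threshold <= 1)
  structure(list(jaccard_threshold = jaccard_threshold,
                 version_insensitive_id = isTRUE(version_insensitive_id)),
            class = "match_config")
}

#' Enumerate overlapping gene pairs between two annotations
#'
#' One row per (A, B) gene pair sharing at least one base on the same
#' chromosome, with the three similarity metrics. Strand is ignored. A-side
#' genes with no overlapping B gene are returned in the
#' `"non_intersecting_a"` attribute.
#'
#' @param genes_a,genes_b gene tables as returned by [read_gene_table()].
#' @param cfg a [match_config()].
#' @return data.frame with columns `a_idx`, `b_idx`, `gene_a_id`,
#'   `gene_a_name`, `gene_b_id`, `gene_b_name`, `name_match`, `id_match`,
#'   `jaccard`; attribute `non_intersecting_a` holds the A gene IDs with no
#'   overlap.
#' @export
overlap_pairs <- function(genes_a, genes_b, cfg = match_config()) {
  stopifnot(nrow(genes_a) > 0, nrow(genes_b) > 0)
  gra <- .as_granges(genes_a$chrom, genes_a$start, genes_a$end)
  grb <- .as_granges(genes_b$chrom, genes_b$start, genes_b$end)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gra, grb, minoverlap = 1L,
                                ignore.strand = TRUE))
  ai <- S4Vectors::queryHits(hits)
  bi <- S4Vectors::subjectHits(hits)
  ida <- genes_a$gene_id[ai]; idb <- genes_b$gene_id[bi]
  if (cfg$version_insensitive_id) {
    idm <- strip_gene_version(ida) == strip_gene_version(idb)
  } else {
    idm <- ida == idb
  }
  pairs <- data.frame(
    a_idx = ai, b_idx = bi,
    gene_a_id = ida, gene_a_name = genes_a$gene_name[ai],
    gene_b_id = idb, gene_b_name = genes_b$gene_name[bi],
    name_match = genes_a$gene_name[ai] == genes_b$gene_name[bi],
    id_match = idm,
    jaccard = jaccard_index(genes_a[ai, c("chrom", "start", "end")],
                            genes_b[bi, c("chrom", "start", "end")]),
    stringsAsFactors = FALSE)
  attr(pairs, "non_intersecting_a") <-
    genes_a$gene_id[setdiff(seq_len(nrow(genes_a)), unique(ai))]
  pairs
}

#' Classify gene pairs into similarity groups
#'
#' Each pair satisfies some subset of the three metrics (name match, ID
#' match, Jaccard index above the threshold); the subset determines a group
#' label 1-8 via binary encoding `4*name + 2*id + jaccard + 1`. Groups whose
#' subset includes a passing Jaccard index are flagged eligible for
#' unambiguous correspondence. Which observed subsets exist (typically six)
#' depends on the data; the numbering here is a canonical reconstruction,
#' not an external standard.
#'
#' @param pairs output of [overlap_pairs()].
#' @param cfg a [match_config()].
#' @return `pairs` with added columns `jaccard_pass`, `group`,
#'   `unambiguous_eligible`; attribute `census` is a data.frame counting
#'   pairs per occupied group.
#' @export
classify_groups <- function(pairs, cfg = match_config()) {
  jp <- pairs$jaccard > cfg$jaccard_threshold
  grp <- 4L * pairs$name_match + 2L * pairs$id_match + as.integer(jp) + 1L
  pairs$jaccard_pass <- jp
  pairs$group <- grp
  pairs$unambiguous_eligible <- jp
  tab <- table(factor(grp, levels = 1:8))
  census <- data.frame(
    group = 1:8,
    name_match = as.logical(bitwAnd(0:7, 4L)),
    id_match = as.logical(bitwAnd(0:7, 2L)),
    jaccard_pass = as.logical(bitwAnd(0:7, 1L)),
    n = as.integer(tab))
  attr(pairs, "census") <- census[census$n > 0, , drop = FALSE]
  pairs
}

#' Resolve gene pairs into a one-to-one correspondence table
#'
#' Stage 1 (primary): each A gene whose pairs include exactly one passing
#' the Jaccard threshold takes that match (`method = "jaccard"`). A genes
#' with several passing pairs are tie-broken deterministically (largest
#' Jaccard index, then lexicographically smallest B gene ID) and recorded in
#' `ambiguous_a`. Stage 2 (fallback): remaining A genes with exactly one
#' name-matching pair take it (`method = "name_fallback"`). Everything else
#' is unmatched. Every A gene appears at most once; B-side uniqueness is not
#' enforced but multiply-used B genes are flagged in `b_reused`.
#'
#' @param pairs output of [classify_groups()] (or [overlap_pairs()]; groups
#'   are computed if absent).
#' @param cfg a [match_config()].
#' @return object of class `correspondence_table`: list with `entries`
#'   (data.frame: `gene_a_id`, `gene_a_name`, `gene_b_id`, `gene_b_name`,
#'   `jaccard`, `method`, `b_reused`), `unmatched_a`, and `ambiguous_a`
#'   (data.frame: `gene_a_id`, `n_candidates`).
#' @export
resolve_one_to_one <- function(pairs, cfg = match_config()) {
  if (is.null(pairs$jaccard_pass)) pairs <- classify_groups(pairs, cfg)
  split_a <- split(seq_len(nrow(pairs)), pairs$gene_a_id)
  entries <- vector("list", length(split_a))
  ambiguous <- list()
  # A genes without any coordinate overlap are unmatched from the start
  unmatched <- as.character(attr(pairs, "non_intersecting_a"))
  for (k in seq_along(split_a)) {
    aid <- names(split_a)[k]
    rows <- split_a[[k]]
    pass <- rows[pairs$jaccard_pass[rows]]
    pick <- NA_integer_; method <- NA_character_
    if (length(pass) == 1L) {
      pick <- pass; method <- "jaccard"
    } else if (length(pass) >= 2L) {
      ord <- pass[order(-pairs$jaccard[pass], pairs$gene_b_id[pass])]
      pick <- ord[1L]; method <- "jaccard"
      ambiguous[[length(ambiguous) + 1L]] <-
        data.frame(gene_a_id = aid, n_candidates = length(pass),
                   stringsAsFactors = FALSE)
    } else {
      nm <- rows[pairs$name_match[rows]]
      if (length(nm) == 1L) { pick <- nm; method <- "name_fallback" }
    }
    if (is.na(pick)) { unmatched <- c(unmatched, aid); next }
    entries[[k]] <- data.frame(
      gene_a_id = aid, gene_a_name = pairs$gene_a_name[pick],
      gene_b_id = pairs$gene_b_id[pick], gene_b_name = pairs$gene_b_name[pick],
      jaccard = pairs$jaccard[pick], method = method, stringsAsFactors = FALSE)
  }
  entries <- do.call(rbind, entries[!vapply(entries, is.null, TRUE)])
  if (is.null(entries))
    entries <- data.frame(gene_a_id = character(), gene_a_name = character(),
                          gene_b_id = character(), gene_b_name = character(),
                          jaccard = numeric(), method = character(),
                          stringsAsFactors = FALSE)
  if (anyDuplicated(entries$gene_a_id))
    stop("internal error: an A gene was matched twice", call. = FALSE)
  entries$b_reused <- entries$gene_b_id %in%
    entries$gene_b_id[duplicated(entries$gene_b_id)]
  ambiguous <- if (length(ambiguous)) do.call(rbind, ambiguous) else
    data.frame(gene_a_id = character(), n_candidates = integer(),
               stringsAsFactors = FALSE)
  structure(list(entries = entries, unmatched_a = unmatched,
                 ambiguous_a = ambiguous, config = cfg),
            class = "correspondence_table")
}

#' @export
print.correspondence_table <- function(x, ...) {
  cat("Gene correspondence table\n")
  cat(sprintf("  matched A genes:   %d (%d via Jaccard, %d via name fallback)\n",
              nrow(x$entries),
              sum(x$entries$method == "jaccard"),
              sum(x$entries$method == "name_fallback")))
  cat(sprintf("  unmatched A genes: %d\n", length(x$unmatched_a)))
  cat(sprintf("  ambiguous A genes: %d (tie-broken deterministically)\n",
              nrow(x$ambiguous_a)))
  if (any(x$entries$b_reused))
    cat(sprintf("  note: %d B genes matched by more than one A gene\n",
                length(unique(x$entries$gene_b_id[x$entries$b_reused]))))
  invisible(x)
}

#' Match two annotations end to end
#'
#' Convenience wrapper: [overlap_pairs()] then [classify_groups()] then
#' [resolve_one_to_one()].
#'
#' @inheritParams overlap_pairs
#' @return a `correspondence_table` (its `pairs` attribute holds the
#'   classified pair table with group census).
#' @export
match_annotations <- function(genes_a, genes_b, cfg = match_config()) {
  pairs <- classify_groups(overlap_pairs(genes_a, genes_b, cfg), cfg)
  out <- resolve_one_to_one(pairs, cfg)
  attr(out, "pairs") <- pairs
  out
}
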