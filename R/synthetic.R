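#' Synthetic data with planted ground truth
#'
#' Desk-scale stand-ins for the two databases: an annotation pair related by
#' renamings, ID version bumps and coordinate jitter with a known true
#' correspondence, and signed peak / contact tables in which some
#' lncRNA x mark pairs are planted as enriched. Everything is deterministic
#' given `seed`.
#'
#' @name synthetic-data
NULL

#' Synthetic scenario configuration
#'
#' Defaults describe the scenario used throughout the test-suite: 30
#' lncRNAs, 3 marks each, 60 peaks per lncRNA x mark pair (half "+"), a
#' planted confirmation probability of 0.8 near "+" peaks and 0.2 near "-"
#' peaks of plus-enriched pairs (swapped for minus-enriched, averaged for
#' null pairs), contacts planted within 25 kb of their peak, and 500 uniform
#' background contacts.
#'
#' @param seed integer seed (mandatory; all outputs are deterministic in it).
#' @param n_chromosomes,chrom_length genome shape for placement.
#' @param n_genes genes in annotation A.
#' @param rename_fraction fraction of B genes given a fresh symbol.
#' @param id_version_bump_fraction fraction of B genes whose ID version is
#'   incremented.
#' @param coord_jitter_sd coordinate noise on B gene boundaries: values
#'   `>= 1` are an absolute SD in bases, values `< 1` a fraction of each
#'   gene's length; draws are truncated at 3 SD so the noise is bounded.
#' @param n_lncrnas number of lncRNAs carrying peaks.
#' @param marks_per_lncrna marks assigned to each lncRNA.
#' @param peaks_per_pair peaks per lncRNA x mark pair.
#' @param plus_fraction fraction of "+" peaks per pair.
#' @param marks histone-mark vocabulary.
#' @param p_confirm_plus,p_confirm_minus planting probabilities of a contact
#'   near a "+" / "-" peak of a plus-enriched pair (must satisfy
#'   `p_confirm_plus >= p_confirm_minus`).
#' @param truth_probs length-3 probabilities for labelling each
#'   lncRNA x mark pair `plus_enriched` / `minus_enriched` / `null`.
#' @param background_contacts uniform background contacts added on top.
#' @param contact_length fixed contact length in bases (short, mimicking
#'   ligation fragments).
#' @param window_truth planting window in bases: a planted contact falls
#'   within this distance of its peak.
#' @param peak_length_range min/max peak length in bases.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             n_chromosomes = 4, chrom_length = 2e7,
                             n_genes = 200,
                             rename_fraction = 0.1,
                             id_version_bump_fraction = 0.3,
                             coord_jitter_sd = 0.002,
                             n_lncrnas = 30, marks_per_lncrna = 3,
                             peaks_per_pair = 60, plus_fraction = 0.5,
                             marks = himorna_marks(),
                             p_confirm_plus = 0.8, p_confirm_minus = 0.2,
                             truth_probs = c(plus = 1/3, minus = 1/3, null = 1/3),
                             background_contacts = 500,
                             contact_length = 100,
                             window_truth = 25000,
                             peak_length_range = c(500, 2000)) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  probs <- c(rename_fraction, id_version_bump_fraction, plus_fraction,
             p_confirm_plus, p_confirm_minus, truth_probs)
  stopifnot(all(probs >= 0), all(probs <= 1),
            p_confirm_plus >= p_confirm_minus,
            marks_per_lncrna <= length(marks),
            length(truth_probs) == 3L)
  structure(as.list(environment()), class = "synthetic_config")
}

# run expr with a private, seeded RNG stream; caller's RNG state untouched
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a pair of gene annotations with known correspondence
#'
#' Annotation A places `n_genes` genes with log-uniform lengths (1-100 kb)
#' on non-overlapping slots so that the Jaccard truth is well defined.
#' Annotation B is A after renaming a fraction of symbols, bumping a
#' fraction of ID versions, jittering boundaries with bounded noise, and
#' shuffling row order. The truth map is the identity correspondence.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `genes_a`, `genes_b` (gene tables) and `truth_map`
#'   (data.frame `gene_a_id`, `gene_b_id`). Warns if the jitter destroys
#'   more than 1\% of the planted Jaccard-threshold matches.
#' @export
generate_annotation_pair <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  .with_seed(cfg$seed, {
    n <- cfg$n_genes
    len <- round(exp(stats::runif(n, log(1000), log(100000))))
    per_chrom <- ceiling(n / cfg$n_chromosomes)
    chrom <- paste0("chr", rep(seq_len(cfg$n_chromosomes), each = per_chrom))[seq_len(n)]
    start <- numeric(n)
    gap <- 10000
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      start[i] <- cumsum(c(gap, len[i[-length(i)]] + gap))
    }
    if (any(start + len > cfg$chrom_length))
      stop("chrom_length too small for n_genes", call. = FALSE)
    genes_a <- data.frame(
      chrom = chrom, start = start, end = start + len,
      gene_id = sprintf("ENSG%011d.1", seq_len(n)),
      gene_name = sprintf("LNC%04d", seq_len(n)),
      strand = sample(c("+", "-"), n, replace = TRUE),
      source_tag = "A", stringsAsFactors = FALSE)

    genes_b <- genes_a
    genes_b$source_tag <- "B"
    ren <- stats::runif(n) < cfg$rename_fraction
    genes_b$gene_name[ren] <- sprintf("NOVEL%04d", which(ren))
    bump <- stats::runif(n) < cfg$id_version_bump_fraction
    genes_b$gene_id[bump] <- sub("\\.1$", ".2", genes_b$gene_id[bump])
    sd_b <- if (cfg$coord_jitter_sd < 1) cfg$coord_jitter_sd * len
            else rep(cfg$coord_jitter_sd, n)
    jit <- function() {
      d <- stats::rnorm(n, 0, sd_b)
      round(pmax(-3 * sd_b, pmin(3 * sd_b, d)))
    }
    genes_b$start <- pmax(0, genes_b$start + jit())
    genes_b$end <- genes_b$end + jit()
    short <- genes_b$end <= genes_b$start
    genes_b$end[short] <- genes_b$start[short] + 1
    truth_map <- data.frame(gene_a_id = genes_a$gene_id,
                            gene_b_id = genes_b$gene_id,
                            stringsAsFactors = FALSE)
    jac <- jaccard_index(genes_a[, c("chrom", "start", "end")],
                         genes_b[, c("chrom", "start", "end")])
    frac_lost <- mean(jac <= 0.99)
    if (frac_lost > 0.01)
      warning(sprintf(
        "coordinate jitter destroyed %.1f%% of planted Jaccard matches",
        100 * frac_lost), call. = FALSE)
    genes_b <- genes_b[sample.int(n), , drop = FALSE]
    rownames(genes_b) <- NULL
    list(genes_a = genes_a, genes_b = genes_b, truth_map = truth_map)
  })
}

#' Generate signed peaks and contacts with planted enrichment
#'
#' Each lncRNA receives `marks_per_lncrna` marks; each lncRNA x mark pair is
#' labelled `plus_enriched`, `minus_enriched` or `null` with `truth_probs`.
#' Peaks of one lncRNA are laid out on slots wide enough
#' (`2*window_truth + slack`) that a contact planted for one peak cannot
#' confirm another peak of the same lncRNA at the truth window. A contact is
#' planted uniformly within `window_truth` of its peak with the
#' sign-dependent probability (so it is always confirmed at
#' `w = window_truth`); null pairs use the average probability for both
#' signs. Uniform background contacts with random lncRNA attribution are
#' added last.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `peaks`, `contacts` and `truth` (data.frame
#'   `lncrna_id`, `mark`, `label`).
#' @export
generate_peaks_and_contacts <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  .with_seed(cfg$seed + 1L, {
    lncs <- sprintf("LNCRNA%04d", seq_len(cfg$n_lncrnas))
    labels <- c("plus_enriched", "minus_enriched", "null")
    truth <- do.call(rbind, lapply(lncs, function(l) {
      data.frame(lncrna_id = l,
                 mark = sample(cfg$marks, cfg$marks_per_lncrna),
                 label = sample(labels, cfg$marks_per_lncrna, replace = TRUE,
                                prob = cfg$truth_probs),
                 stringsAsFactors = FALSE)
    }))
    n_pairs <- nrow(truth)
    npk <- cfg$peaks_per_pair
    n_plus <- round(cfg$plus_fraction * npk)
    slot <- 2 * cfg$window_truth + 2 * cfg$contact_length +
      cfg$peak_length_range[2] + 1000

    peaks <- vector("list", n_pairs)
    contacts <- vector("list", n_pairs)
    pk0 <- 0L
    for (j in seq_len(n_pairs)) {
      lnc_idx <- match(truth$lncrna_id[j], lncs)
      pair_in_lnc <- sum(truth$lncrna_id[seq_len(j)] == truth$lncrna_id[j])
      sign <- c(rep("+", n_plus), rep("-", npk - n_plus))
      plen <- round(stats::runif(npk, cfg$peak_length_range[1],
                                 cfg$peak_length_range[2]))
      # deterministic slotting: peak i of this pair occupies slot index
      # (pair_in_lnc - 1) * npk + i within its lncRNA's private layout
      slot_idx <- (pair_in_lnc - 1L) * npk + seq_len(npk) - 1L
      chrom_i <- (slot_idx %% cfg$n_chromosomes) + 1L
      row_i <- slot_idx %/% cfg$n_chromosomes
      start <- row_i * slot + cfg$window_truth + cfg$contact_length +
        round(stats::runif(npk, 0, 500))
      if (any(start + plen > cfg$chrom_length))
        stop("chrom_length too small for this peak layout", call. = FALSE)
      peaks[[j]] <- data.frame(
        chrom = paste0("chr", chrom_i), start = start, end = start + plen,
        mark = truth$mark[j], sign = sign,
        peak_id = sprintf("peak_%06d", pk0 + seq_len(npk)),
        lncrna_id = truth$lncrna_id[j],
        associated_gene = NA_character_, stringsAsFactors = FALSE)
      pk0 <- pk0 + npk

      p_null <- (cfg$p_confirm_plus + cfg$p_confirm_minus) / 2
      p <- switch(truth$label[j],
        plus_enriched = ifelse(sign == "+", cfg$p_confirm_plus, cfg$p_confirm_minus),
        minus_enriched = ifelse(sign == "+", cfg$p_confirm_minus, cfg$p_confirm_plus),
        null = rep(p_null, npk))
      place <- stats::runif(npk) < p
      if (any(place)) {
        lo <- pmax(0, start[place] - cfg$window_truth)
        hi <- start[place] + plen[place] + cfg$window_truth - 1
        cx <- floor(stats::runif(sum(place), lo, hi))
        contacts[[j]] <- data.frame(
          chrom = paste0("chr", chrom_i[place]),
          start = cx, end = cx + cfg$contact_length,
          lncrna_id = truth$lncrna_id[j],
          experiment_id = sprintf("exp%d", sample(1:4, sum(place), replace = TRUE)),
          stringsAsFactors = FALSE)
      }
    }
    peaks <- do.call(rbind, peaks)
    contacts <- do.call(rbind, contacts[!vapply(contacts, is.null, TRUE)])
    if (cfg$background_contacts > 0) {
      nb <- cfg$background_contacts
      bx <- floor(stats::runif(nb, 0, cfg$chrom_length - cfg$contact_length))
      bg <- data.frame(
        chrom = paste0("chr", sample.int(cfg$n_chromosomes, nb, replace = TRUE)),
        start = bx, end = bx + cfg$contact_length,
        lncrna_id = sample(lncs, nb, replace = TRUE),
        experiment_id = "exp_bg", stringsAsFactors = FALSE)
      contacts <- rbind(contacts, bg)
    }
    rownames(peaks) <- NULL
    if (!is.null(contacts)) rownames(contacts) <- NULL
    list(peaks = peaks,
         contacts = if (is.null(contacts))
           data.frame(chrom = character(), start = numeric(), end = numeric(),
                      lncrna_id = character(), experiment_id = character(),
                      stringsAsFactors = FALSE) else contacts,
         truth = truth)
  })
}
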