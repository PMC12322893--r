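# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (no findOverlaps, no phyper): per-base set arithmetic,
# all-pairs loops, and hypergeometric enumeration via choose().

# Jaccard via explicit per-base sets (intervals half-open)
brute_jaccard <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  sa <- seq(a$start, a$end - 1)
  sb <- seq(b$start, b$end - 1)
  ov <- length(intersect(sa, sb))
  if (ov == 0) return(0)
  ov / length(union(sa, sb))
}

# all-pairs confirmation: gap <= w - 1 or overlap, same chrom and lncRNA
brute_confirm <- function(peaks, contacts, w) {
  out <- rep(FALSE, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(contacts))) {
      if (peaks$lncrna_id[i] != contacts$lncrna_id[j]) next
      if (peaks$chrom[i] != contacts$chrom[j]) next
      gap <- max(peaks$start[i] - contacts$end[j],
                 contacts$start[j] - peaks$end[i])
      if (gap < w) { out[i] <- TRUE; break }   # gap <= w - 1, or overlap (gap < 0)
    }
  }
  out
}

# exact hypergeometric tails by probability-mass enumeration over choose()
brute_fisher_tails <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0) return(c(right = 1, left = 1))
  xs <- max(0, k - n):min(k, m)
  pm <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  c(right = sum(pm[xs >= a]), left = sum(pm[xs <= a]))
}

# random peak/contact fixture sharing a small lncRNA namespace
random_peak_contact_fixture <- function(n_peaks, n_contacts, n_lnc = 3,
                                        n_chrom = 2, span = 200000) {
  peaks <- data.frame(
    chrom = paste0("chr", sample.int(n_chrom, n_peaks, replace = TRUE)),
    start = s <- sample.int(span, n_peaks, replace = TRUE),
    end = s + sample(50:2000, n_peaks, replace = TRUE),
    mark = sample(himorna_marks(), n_peaks, replace = TRUE),
    sign = sample(c("+", "-"), n_peaks, replace = TRUE),
    peak_id = sprintf("p%04d", seq_len(n_peaks)),
    lncrna_id = sample(paste0("L", seq_len(n_lnc)), n_peaks, replace = TRUE),
    associated_gene = NA_character_, stringsAsFactors = FALSE)
  contacts <- data.frame(
    chrom = paste0("chr", sample.int(n_chrom, n_contacts, replace = TRUE)),
    start = cs <- sample.int(span, n_contacts, replace = TRUE),
    end = cs + sample(50:500, n_contacts, replace = TRUE),
    lncrna_id = sample(paste0("L", seq_len(n_lnc)), n_contacts, replace = TRUE),
    experiment_id = "e1", stringsAsFactors = FALSE)
  list(peaks = peaks, contacts = contacts)
}

# minimal gene table constructor for matching tests
gene_table <- function(chrom, start, end, gene_id, gene_name,
                       strand = "+", source_tag = "A") {
  data.frame(chrom = chrom, start = start, end = end, gene_id = gene_id,
             gene_name = gene_name, strand = strand, source_tag = source_tag,
             stringsAsFactors = FALSE)
}
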