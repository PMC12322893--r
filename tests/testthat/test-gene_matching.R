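test_that("jaccard_index handles identity, disjoint chromosomes and overlap", {
  iv <- function(c, s, e) genomic_interval(c, s, e)
  expect_equal(jaccard_index(iv("chr1", 0, 100), iv("chr1", 0, 100)), 1.0)
  expect_equal(jaccard_index(iv("chr1", 0, 100), iv("chr2", 0, 100)), 0.0)
  expect_equal(jaccard_index(iv("chr1", 0, 100), iv("chr1", 50, 150)), 50 / 150)
  expect_equal(jaccard_index(iv("chr1", 0, 100), iv("chr1", 100, 200)), 0.0)  # adjacency
  # symmetry
  expect_equal(jaccard_index(iv("chr1", 10, 80), iv("chr1", 5, 40)),
               jaccard_index(iv("chr1", 5, 40), iv("chr1", 10, 80)))
})

test_that("jaccard_index agrees with per-base set oracle on short intervals", {
  set.seed(13)
  for (i in 1:300) {
    s1 <- sample.int(300, 1); e1 <- s1 + sample.int(200, 1)
    s2 <- sample.int(300, 1); e2 <- s2 + sample.int(200, 1)
    c1 <- sample(c("chr1", "chr2"), 1); c2 <- sample(c("chr1", "chr2"), 1)
    a <- genomic_interval(c1, s1, e1); b <- genomic_interval(c2, s2, e2)
    expect_equal(jaccard_index(a, b),
                 brute_jaccard(list(chrom = c1, start = s1, end = e1),
                               list(chrom = c2, start = s2, end = e2)))
  }
})

test_that("overlap_pairs enumerates multi-hits and reports non-intersecting genes", {
  a <- gene_table("chr1", c(100, 5000), c(1000, 6000),
                  c("ENSGA.1", "ENSGB.1"), c("GA", "GB"))
  b <- gene_table("chr1", c(100, 500, 20000), c(600, 1000, 21000),
                  c("ENSGA.2", "ENSGX.1", "ENSGY.1"), c("GA", "GX", "GY"),
                  source_tag = "B")
  p <- overlap_pairs(a, b)
  expect_equal(nrow(p), 2)                              # one A gene, two hits
  expect_setequal(p$gene_b_id, c("ENSGA.2", "ENSGX.1"))
  expect_equal(attr(p, "non_intersecting_a"), "ENSGB.1")
  expect_true(p$id_match[p$gene_b_id == "ENSGA.2"])     # version-insensitive
  expect_false(any(p$id_match[p$gene_b_id == "ENSGX.1"]))

  # identical annotations self-match with all flags true
  p2 <- overlap_pairs(a, transform(a, source_tag = "B"))
  expect_equal(nrow(p2), 2)
  expect_true(all(p2$name_match & p2$id_match & p2$jaccard == 1))
})

test_that("classify_groups census covers the occupied metric triples", {
  # six pairs covering six distinct (name, id, jaccard) triples
  mk <- function(name_b, id_b, s_b, e_b)
    list(a = gene_table("chr1", 0, 1000, "ENSG1.1", "G1"),
         b = gene_table("chr1", s_b, e_b, id_b, name_b, source_tag = "B"))
  cases <- list(
    mk("G1", "ENSG1.2", 0, 1000),      # TTT
    mk("G1", "ENSG1.2", 0, 500),       # TTF
    mk("G1", "ENSGZ.1", 0, 1000),      # TFT
    mk("G1", "ENSGZ.1", 0, 500),       # TFF
    mk("GZ", "ENSG1.2", 0, 1000),      # FTT
    mk("GZ", "ENSGZ.1", 0, 500))       # FFF
  pairs <- do.call(rbind, lapply(cases, function(x) overlap_pairs(x$a, x$b)))
  cl <- classify_groups(pairs)
  census <- attr(cl, "census")
  expect_equal(nrow(census), 6)
  expect_true(all(census$n == 1))
  expect_equal(sum(census$n), nrow(pairs))
  expect_identical(cl$unambiguous_eligible, cl$jaccard_pass)
  # eligibility tracks the jaccard metric only
  expect_false(cl$unambiguous_eligible[4])   # name-only pair
  expect_true(cl$unambiguous_eligible[5])
})

test_that("resolve_one_to_one applies the two-stage rule and the tie-break", {
  a <- gene_table("chr1", c(0, 10000, 30000), c(1000, 11000, 31000),
                  c("A1.1", "A2.1", "A3.1"), c("N1", "N2", "N3"))
  # A1: one perfect jaccard match; A2: fails jaccard, unique name match;
  # A3: two perfect jaccard candidates with distinct IDs
  b <- gene_table("chr1",
                  c(0, 10000, 30000, 30000),
                  c(1000, 10500, 31000, 31000),
                  c("B1.1", "B2.1", "B3b.1", "B3a.1"),
                  c("N1", "N2", "NZ", "NY"), source_tag = "B")
  ct <- resolve_one_to_one(overlap_pairs(a, b))
  e <- ct$entries
  expect_equal(e$gene_b_id[e$gene_a_id == "A1.1"], "B1.1")
  expect_equal(e$method[e$gene_a_id == "A1.1"], "jaccard")
  expect_equal(e$method[e$gene_a_id == "A2.1"], "name_fallback")
  # tie at jaccard 1.0 broken to lexicographically smallest B id
  expect_equal(e$gene_b_id[e$gene_a_id == "A3.1"], "B3a.1")
  expect_equal(ct$ambiguous_a$gene_a_id, "A3.1")
  expect_equal(ct$ambiguous_a$n_candidates, 2)
  # A genes appear at most once
  expect_false(anyDuplicated(e$gene_a_id) > 0)
})

test_that("unmatched genes are reported and B reuse is flagged, not forbidden", {
  a <- gene_table("chr1", c(0, 100000), c(1000, 101000),
                  c("A1.1", "A2.1"), c("N1", "N2"))
  b <- gene_table("chr1", 0, 1000, "B1.1", "NX", source_tag = "B")
  ct <- match_annotations(a, b)
  expect_equal(ct$unmatched_a, "A2.1")        # no overlap, no name
  expect_equal(nrow(ct$entries), 1)

  # two A genes onto one B gene
  a2 <- gene_table("chr1", c(0, 10), c(1000, 990),
                   c("A1.1", "A2.1"), c("N1", "N2"))
  b2 <- gene_table("chr1", 0, 1000, "B1.1", "N1", source_tag = "B")
  ct2 <- resolve_one_to_one(
    overlap_pairs(a2, b2, match_config(jaccard_threshold = 0.9)),
    match_config(jaccard_threshold = 0.9))
  expect_equal(nrow(ct2$entries), 2)
  expect_true(all(ct2$entries$b_reused))
})

test_that("planted correspondences are recovered from jittered annotations", {
  cfg <- synthetic_config(seed = 5, n_genes = 150, rename_fraction = 1.0,
                          coord_jitter_sd = 0)
  ap <- generate_annotation_pair(cfg)
  ct <- match_annotations(ap$genes_a, ap$genes_b)
  got <- ct$entries[match(ap$truth_map$gene_a_id, ct$entries$gene_a_id), ]
  # full rename, zero jitter: names useless, coordinates recover everything
  expect_equal(got$gene_b_id, ap$truth_map$gene_b_id)
  expect_true(all(got$method == "jaccard"))
})
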