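test_that("extend_interval widens symmetrically with a left clamp at zero", {
  iv <- genomic_interval("chr13", 21045571, 21046978)
  ext <- extend_interval(iv, 25000)
  expect_equal(c(ext$start, ext$end), c(21020571, 21071978))
  expect_equal(extend_interval(iv, 0), iv)                # identity at w = 0
  ext2 <- extend_interval(genomic_interval("chr1", 10, 20), 100)
  expect_equal(c(ext2$start, ext2$end), c(0, 120))        # left clamp
  ext3 <- extend_interval(genomic_interval("chr1", 10, 20), 100,
                          chrom_sizes = c(chr1 = 80))
  expect_equal(ext3$end, 80)                              # right clamp opt-in
})

test_that("confirmation requires same lncRNA and reach within the window", {
  pk <- data.frame(chrom = "chr1", start = 1000, end = 2000, mark = "H3K27ac",
                   sign = "+", peak_id = "p1", lncrna_id = "L1",
                   associated_gene = NA, stringsAsFactors = FALSE)
  ct <- data.frame(chrom = "chr1", start = 5000, end = 5100,
                   lncrna_id = "L1", experiment_id = "e1",
                   stringsAsFactors = FALSE)
  expect_false(confirm_peaks(pk, ct, 1000))   # gap 3000 > 1000
  expect_true(confirm_peaks(pk, ct, 5000))    # extended contact reaches back
  expect_false(confirm_peaks(pk, ct, 3000))   # gap 3000 needs w >= 3001
  expect_true(confirm_peaks(pk, ct, 3001))
  # identical geometry, wrong lncRNA: never confirms
  ct2 <- transform(pk[, c("chrom", "start", "end")], lncrna_id = "L2",
                   experiment_id = "e1")
  expect_false(confirm_peaks(pk, ct2, 50000))
  # adjacency at w = 0 does not confirm (half-open, >= 1 shared base)
  ct3 <- data.frame(chrom = "chr1", start = 2000, end = 2100,
                    lncrna_id = "L1", experiment_id = "e1",
                    stringsAsFactors = FALSE)
  expect_false(confirm_peaks(pk, ct3, 0))
  expect_true(confirm_peaks(pk, ct3, 1))
})

test_that("confirm_peaks agrees with the all-pairs brute-force oracle", {
  set.seed(31)
  for (rep in 1:6) {
    fx <- random_peak_contact_fixture(n_peaks = 400, n_contacts = 400)
    w <- sample(c(0, 1, 137, 1000, 25000), 1)
    expect_identical(confirm_peaks(fx$peaks, fx$contacts, w),
                     brute_confirm(fx$peaks, fx$contacts, w))
  }
})

test_that("extending peaks or contacts by w gives identical verdicts", {
  set.seed(41)
  for (rep in 1:5) {
    fx <- random_peak_contact_fixture(n_peaks = 200, n_contacts = 200)
    w <- sample(c(1000, 5000, 25000), 1)
    by_contacts <- confirm_peaks(fx$peaks, fx$contacts, w)
    pk_ext <- fx$peaks
    ext <- extend_interval(pk_ext[, c("chrom", "start", "end")], w)
    pk_ext$start <- ext$start; pk_ext$end <- ext$end
    by_peaks <- confirm_peaks(pk_ext, fx$contacts, 0)
    expect_identical(by_contacts, by_peaks)
  }
})

test_that("confirmation is independent of input row order", {
  set.seed(51)
  fx <- random_peak_contact_fixture(n_peaks = 150, n_contacts = 150)
  base <- confirm_peaks(fx$peaks, fx$contacts, 5000)
  perm <- sample.int(nrow(fx$peaks))
  permc <- sample.int(nrow(fx$contacts))
  expect_identical(confirm_peaks(fx$peaks[perm, ], fx$contacts[permc, ], 5000),
                   base[perm])
})

test_that("confirmation proportions sweep matches hand counts and is monotone", {
  # 4 peaks of one lncRNA: contacts cover 2 at w = 0 and 3 at w = 25 kb
  pk <- data.frame(chrom = "chr1",
                   start = c(1000, 100000, 200000, 300000),
                   end = c(2000, 101000, 201000, 301000),
                   mark = "H3K27ac", sign = "+",
                   peak_id = paste0("p", 1:4), lncrna_id = "L1",
                   associated_gene = NA, stringsAsFactors = FALSE)
  ct <- data.frame(chrom = "chr1",
                   start = c(1500, 100100, 220000),
                   end = c(1600, 100200, 220100),
                   lncrna_id = "L1", experiment_id = "e1",
                   stringsAsFactors = FALSE)
  sw <- confirmation_sweep(pk, ct, windows = c(0, 25000))
  expect_equal(sw$proportion[sw$window == 0], 0.5)
  expect_equal(sw$proportion[sw$window == 25000], 0.75)

  # no contacts: all zero; blanket coverage: all one
  sw0 <- confirmation_sweep(pk, ct[0, ], windows = c(0, 25000))
  expect_true(all(sw0$proportion == 0))
  ct_all <- data.frame(chrom = "chr1", start = pk$start, end = pk$end,
                       lncrna_id = "L1", experiment_id = "e1",
                       stringsAsFactors = FALSE)
  sw1 <- confirmation_sweep(pk, ct_all, windows = c(0, 50000))
  expect_true(all(sw1$proportion == 1))

  # lncRNA with no peaks is flagged
  sw2 <- confirmation_sweep(pk, ct, windows = 0, lncrnas = c("L1", "L9"))
  expect_true(sw2$no_peaks[sw2$lncrna_id == "L9"])
  expect_true(is.na(sw2$proportion[sw2$lncrna_id == "L9"]))
})

test_that("confirmed sets grow with the window on random fixtures", {
  set.seed(61)
  windows <- c(0, 1000, 5000, 10000, 25000, 50000)
  for (rep in 1:20) {
    fx <- random_peak_contact_fixture(n_peaks = 80, n_contacts = 40)
    prev <- rep(FALSE, nrow(fx$peaks))
    for (w in windows) {
      cur <- confirm_peaks(fx$peaks, fx$contacts, w)
      expect_true(all(cur[prev]))   # subset relation, not just proportions
      prev <- cur
    }
  }
})

test_that("lncRNA-level summary counts contacts and confirmations", {
  set.seed(71)
  fx <- random_peak_contact_fixture(n_peaks = 60, n_contacts = 30, n_lnc = 10)
  s <- lncrna_level_summary(fx$peaks, fx$contacts, 25000)
  expect_lte(s$n_with_confirmed_peak, s$n_with_any_contact)
  expect_equal(s$fraction_confirmed,
               s$n_with_confirmed_peak / s$n_with_any_contact)

  # contact-free world
  s0 <- lncrna_level_summary(fx$peaks, fx$contacts[0, ], 25000)
  expect_equal(s0$n_with_any_contact, 0)
  expect_true(s0$undefined)

  # one fully confirmed lncRNA
  pk <- fx$peaks[fx$peaks$lncrna_id == fx$peaks$lncrna_id[1], ]
  ctc <- data.frame(chrom = pk$chrom, start = pk$start, end = pk$end,
                    lncrna_id = pk$lncrna_id, experiment_id = "e1",
                    stringsAsFactors = FALSE)
  s1 <- lncrna_level_summary(pk, ctc, 0)
  expect_equal(unlist(s1[c("n_with_any_contact", "n_with_confirmed_peak",
                           "fraction_confirmed")]),
               c(n_with_any_contact = 1, n_with_confirmed_peak = 1,
                 fraction_confirmed = 1))
})
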