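toy_window <- function() {
  # donor window, GT at positions 4-5, motif span (3, 6) covers the window
  splice_window("ACAGTAAGT", "donor_5ss", dinucleotide_start = 4)
}

test_that("window construction validates the consensus dinucleotide and anchor", {
  expect_error(splice_window("ACAATAAGT", "donor_5ss", dinucleotide_start = 4),
               "expected GT")
  expect_error(splice_window("ACAGTAAGT", "donor_5ss", dinucleotide_start = 4,
                             anchor_position = 5), "dinucleotide")
  w <- splice_window("ACAGTAAGT", "donor_5ss", dinucleotide_start = 4,
                     anchor_position = 2)
  expect_equal(w$anchor_position, 2L)
})

test_that("single-sequence training with uniform background is hand-computable", {
  # one 2-mer site "AG", pseudocount 1 distributed by a uniform background:
  # f(observed) = (1 + 0.25) / 2 = 0.625, f(other) = 0.125
  m <- train_scorer("AG", decoys = NULL, model_type = "wmm",
                    site_type = "donor_5ss", pseudocount = 1,
                    span = c(exonic = 1, intronic = 1))
  expect_equal(unname(m$params$freqs[1, ]), c(0.625, 0.125, 0.125, 0.125))
  expect_equal(unname(m$params$freqs[2, ]), c(0.125, 0.125, 0.625, 0.125))
  expect_true(all(abs(rowSums(m$params$freqs) - 1) < 1e-9))
  # scoring the consensus "AG" at the motif positions: 2 * log2(0.625 / 0.25)
  w <- splice_window("AGTC", "donor_5ss", dinucleotide_start = 2)
  expect_equal(splice_score(m, w), 2 * log2(2.5))
})

test_that("sites matching the decoy composition score zero everywhere", {
  m <- train_scorer(c("AA", "CC", "GG", "TT"), decoys = "ACGT",
                    model_type = "wmm", site_type = "donor_5ss",
                    span = c(exonic = 1, intronic = 1))
  expect_true(all(abs(m$params$logodds) < 1e-12))
  w <- splice_window("AGTC", "donor_5ss", dinucleotide_start = 2)
  expect_equal(splice_score(m, w), 0)
  expect_equal(splice_score(m, w, haplotype_edit(1, "C")), 0)
})

test_that("training recovers a known frequency table at large n", {
  truth <- matrix(c(0.7, 0.1, 0.1, 0.1,
                    0.1, 0.6, 0.2, 0.1), nrow = 2, byrow = TRUE)
  sites <- withr::with_seed(31, {
    vapply(1:10000, function(i) {
      paste(c(sample(c("A", "C", "G", "T"), 1, prob = truth[1, ]),
              sample(c("A", "C", "G", "T"), 1, prob = truth[2, ])), collapse = "")
    }, character(1))
  })
  m <- train_scorer(sites, decoys = NULL, model_type = "wmm",
                    site_type = "donor_5ss", span = c(exonic = 1, intronic = 1))
  expect_true(all(abs(m$params$freqs - truth) < 0.02))
})

test_that("a strictly consensus-peaked model is maximal at the consensus", {
  m <- train_scorer(rep("CAGGTAAGT", 50), decoys = NULL, model_type = "wmm",
                    site_type = "donor_5ss")
  w <- splice_window("CAGGTAAGT", "donor_5ss", dinucleotide_start = 4)
  ref <- splice_score(m, w)
  for (pos in 1:9) {
    for (alt in setdiff(c("A", "C", "G", "T"), w$sequence[pos])) {
      expect_lt(splice_score(m, w, haplotype_edit(pos, alt)), ref)
    }
  }
})

test_that("WMM score deltas equal per-position log-odds lookups for random edits", {
  withr::with_seed(17, {
    sites <- vapply(1:30, function(i) {
      paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE), collapse = "")
    }, character(1))
    m <- train_scorer(sites, decoys = c("ACGTACGTGCAT"), model_type = "wmm",
                      site_type = "donor_5ss")
    w <- toy_window()
    ref <- splice_score(m, w)
    for (i in 1:50) {
      npos <- sample(1:4, 1)
      pos <- sample(1:9, npos)
      alt <- vapply(pos, function(p) {
        sample(setdiff(c("A", "C", "G", "T"), w$sequence[p]), 1)
      }, character(1))
      edits <- haplotype_edit(pos, alt)
      delta_lookup <- sum(vapply(seq_len(npos), function(j) {
        bases <- c("A", "C", "G", "T")
        m$params$logodds[pos[j], match(alt[j], bases)] -
          m$params$logodds[pos[j], match(w$sequence[pos[j]], bases)]
      }, numeric(1)))
      expect_equal(splice_score(m, w, edits) - ref, delta_lookup)
    }
  })
})

test_that("compound impact is additive for a WMM and anchor-neutral out of span", {
  m <- train_scorer(rep("CAGGTAAGT", 10), decoys = NULL, model_type = "wmm",
                    site_type = "donor_5ss")
  # window longer than the motif: positions 1-3 lie outside the 9-mer span
  w <- splice_window("TTTACAGGTAAGTTT", "donor_5ss", dinucleotide_start = 8)
  variant <- haplotype_edit(6, "T")   # in-span (span covers 5..13)
  anchor_out <- haplotype_edit(2, "A")
  ci <- compound_impact(m, w, variant, anchor_out)
  expect_equal(ci$delta_haplotype, ci$delta_variant)
  anchor_in <- haplotype_edit(12, "C")
  ci2 <- compound_impact(m, w, variant, anchor_in)
  anchor_solo <- splice_score(m, w, anchor_in) - splice_score(m, w)
  expect_equal(ci2$delta_haplotype, ci2$delta_variant + anchor_solo)
})

test_that("WAM scores match an independent chain computation", {
  withr::with_seed(53, {
    sites <- vapply(1:200, function(i) {
      paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE,
                   prob = c(0.4, 0.3, 0.2, 0.1)), collapse = "")
    }, character(1))
    m <- train_scorer(sites, decoys = sites, model_type = "wam",
                      site_type = "donor_5ss")
    w <- toy_window()
    chain_score <- function(chars) {
      bases <- c("A", "C", "G", "T")
      idx <- match(chars, bases)
      s <- log2(m$params$marginal[idx[1]] / m$background[idx[1]])
      for (p in 2:9) {
        s <- s + log2(m$params$conditional[[p - 1]][idx[p - 1], idx[p]] /
                        m$background[idx[p]])
      }
      unname(s)
    }
    expect_equal(splice_score(m, w), chain_score(w$sequence))
    # adjacent variant/anchor: additivity fails in general, direct scoring is
    # the only oracle
    v <- haplotype_edit(6, "C")
    a <- haplotype_edit(7, "C")
    ci <- compound_impact(m, w, v, a)
    edited <- w$sequence
    edited[6:7] <- "C"
    expect_equal(ci$delta_haplotype, chain_score(edited) - chain_score(w$sequence))
  })
})

test_that("a variant's impact is reported on the strongest splice site only", {
  strong <- train_scorer(rep("CAGGTAAGT", 20), decoys = NULL,
                         model_type = "wmm", site_type = "donor_5ss")
  weak_sites <- c(paste0(strrep("T", 18), "AGGTC"), paste0(strrep("G", 18), "AGGTC"))
  acc <- train_scorer(weak_sites, decoys = NULL, model_type = "wmm",
                      site_type = "acceptor_3ss")
  wd <- splice_window("CAGGTAAGT", "donor_5ss", dinucleotide_start = 4)
  wa <- splice_window(paste0(strrep("T", 18), "AGGTC"), "acceptor_3ss",
                      dinucleotide_start = 19)
  models <- list(donor_5ss = strong, acceptor_3ss = acc)
  windows <- list(donor_5ss = wd, acceptor_3ss = wa)
  # variant maps only into the donor window
  only_donor <- strongest_site(models, windows,
                               list(donor_5ss = haplotype_edit(2, "T")))
  expect_equal(only_donor$site_type, "donor_5ss")
  # donor reference score is higher here, so the donor is reported
  both <- strongest_site(models, windows,
                         list(donor_5ss = haplotype_edit(2, "T"),
                              acceptor_3ss = haplotype_edit(2, "C")))
  expect_equal(both$site_type,
               names(which.max(both$reference_scores)))
  # exact tie (two all-zero models) breaks towards the acceptor
  zero_d <- train_scorer(c("AA", "CC", "GG", "TT"), decoys = "ACGT",
                         model_type = "wmm", site_type = "donor_5ss",
                         span = c(exonic = 1, intronic = 1))
  zero_a <- train_scorer(c("AA", "CC", "GG", "TT"), decoys = "ACGT",
                         model_type = "wmm", site_type = "acceptor_3ss",
                         span = c(exonic = 1, intronic = 1))
  tie <- strongest_site(list(donor_5ss = zero_d, acceptor_3ss = zero_a),
                        list(donor_5ss = splice_window("AGTC", "donor_5ss",
                                                       dinucleotide_start = 2),
                             acceptor_3ss = splice_window("CAGT", "acceptor_3ss",
                                                          dinucleotide_start = 2)),
                        list(donor_5ss = haplotype_edit(1, "C"),
                             acceptor_3ss = haplotype_edit(1, "G")))
  expect_equal(tie$site_type, "acceptor_3ss")
})

test_that("minus-strand windows score identically to transcript-orientation construction", {
  withr::with_seed(71, {
    # transcript-oriented window, then its reverse complement as plus-strand genome
    w_direct <- random_window(21, "donor_5ss")
    tx <- paste(w_direct$sequence, collapse = "")
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    plus_strand <- paste(rev(comp[w_direct$sequence]), collapse = "")
    w_minus <- window_from_genome(plus_strand, 1, 21, "-", "donor_5ss",
                                  dinucleotide_start = w_direct$dinucleotide_start)
    expect_equal(paste(w_minus$sequence, collapse = ""), tx)
    sites <- vapply(1:20, function(i) {
      paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE), collapse = "")
    }, character(1))
    m <- train_scorer(sites, decoys = NULL, model_type = "wmm",
                      site_type = "donor_5ss")
    edit <- haplotype_edit(3, setdiff(c("A", "C", "G", "T"), w_direct$sequence[3])[1])
    expect_equal(splice_score(m, w_minus, edit), splice_score(m, w_direct, edit))
    # genome map points back to the plus strand in descending order
    expect_equal(w_minus$genome_map$genomic_position, 21:1)
  })
})

test_that("a multi-edit haplotype scores like sequential single edits", {
  withr::with_seed(83, {
    w <- random_window(45, "acceptor_3ss")
    sites <- vapply(1:20, function(i) {
      paste(sample(c("A", "C", "G", "T"), 23, replace = TRUE), collapse = "")
    }, character(1))
    m <- train_scorer(sites, decoys = NULL, model_type = "wam",
                      site_type = "acceptor_3ss")
    pos <- c(3, 10)
    alt <- vapply(pos, function(p) {
      sample(setdiff(c("A", "C", "G", "T"), w$sequence[p]), 1)
    }, character(1))
    both <- splice_score(m, w, haplotype_edit(pos, alt))
    intermediate <- splice_window(paste(apply_edits(w, haplotype_edit(pos[1], alt[1])),
                                        collapse = ""),
                                  "acceptor_3ss",
                                  dinucleotide_start = w$dinucleotide_start)
    sequential <- splice_score(m, intermediate, haplotype_edit(pos[2], alt[2]))
    expect_equal(both, sequential)
  })
})

test_that("scorer models survive a plain-text serialization round trip", {
  withr::with_seed(97, {
    sites <- vapply(1:40, function(i) {
      paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE), collapse = "")
    }, character(1))
    decoys <- vapply(1:10, function(i) {
      paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
    }, character(1))
    w <- toy_window()
    for (type in c("wmm", "wam")) {
      m <- train_scorer(sites, decoys, model_type = type, site_type = "donor_5ss")
      tmp <- tempfile()
      write_scorer_model(m, tmp)
      m2 <- read_scorer_model(tmp)
      expect_equal(m2$model_type, type)
      expect_equal(splice_score(m2, w), splice_score(m, w))
      expect_equal(splice_score(m2, w, haplotype_edit(2, "T")),
                   splice_score(m, w, haplotype_edit(2, "T")))
    }
  })
})

test_that("edits identical to the reference base are rejected", {
  w <- toy_window()
  expect_error(apply_edits(w, haplotype_edit(1, "A")), "identical to the reference")
  expect_error(haplotype_edit(c(2, 2), c("T", "G")), "distinct")
})
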