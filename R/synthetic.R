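#' Default haplotype pool of the bundled scenario
#'
#' Six recurring multi-variant cis-haplotypes echoing the structure of the
#' cohort catalog: common anchors (the synonymous exon-10 allele, the distal
#' enhancer allele, and the GOLD-domain missense allele) travelling with rare
#' missense and structural variants, plus the frequent two-anchor
#' enhancer/synonymous haplotype. Frequencies sum to 0.42; the remaining 0.58
#' is the reference haplotype.
#'
#' @return Named list of `list(members, frequency)` entries.
#' @keywords internal
default_haplotype_pool <- function() {
  list(
    ala355_val443 = list(members = c("rs1800404", "c.1327G>A"), frequency = 0.10),
    gly27_ala355_leu440 = list(members = c("c.79G>A", "rs1800404", "c.1320G>C"),
                               frequency = 0.06),
    gly27_ex14del = list(members = c("c.79G>A", "g.27979571_27984604del"),
                         frequency = 0.04),
    arg305_ex7del = list(members = c("rs1800401", "g.28017719_28020678delinsTTT"),
                         frequency = 0.06),
    blue_ala355 = list(members = c("rs12913832", "rs1800404"), frequency = 0.14),
    arg243_ala355 = list(members = c("rs1800404", "c.727C>T"), frequency = 0.02)
  )
}

#' Scenario configuration for the synthetic-data generators
#'
#' Bundles every tunable of the generators with defaults emulating the study
#' conditions: a six-haplotype pool over the five GWAS anchor sites and rare
#' variants, full-trio phasing availability where stated, 30x fragment depth
#' with 2% per-observation error, 162-bp splice windows with an exonic anchor
#' shared by the donor and acceptor windows, a multiplicative dosage model
#' (baseline 100 TPM, per-allele retention 0.73, log-noise 0.15), LRR shifts
#' of -0.45 (one-copy) and -2.0 (two-copy loss) with probe noise 0.15, and a
#' phased panel of 2504 individuals.
#'
#' @param seed Integer master seed; each generator derives its own sub-stream,
#'   so adding one generator never perturbs another's output.
#' @param n_probands Number of cohort probands.
#' @param trio_fraction Fraction of probands with parental genotypes.
#' @param fragment_depth Read fragments simulated per variant pair.
#' @param fragment_error Per-observation allele error rate.
#' @param haplotype_pool Named list of `list(members, frequency)`; frequencies
#'   must sum to <= 1 (remainder = reference haplotype).
#' @param variants A `variant_table` resolving every pool member (default: the
#'   packaged cohort annotation table).
#' @param motif_peak Consensus-base probability of the splice motif frequency
#'   tables.
#' @param n_training Training sequences sampled per motif model.
#' @param flank Splice-window flank size (80 gives the 162-bp geometry).
#' @param exon_length Length of the synthetic exon between the two sites.
#' @param dosage A [dosage_model()].
#' @param expr_n_per_dosage Expression samples per dosage group.
#' @param lrr_shift_het,lrr_shift_hom Mean LRR shifts for copy number 1 / 0.
#' @param lrr_noise_sd Per-probe LRR noise standard deviation.
#' @param lrr_probes Probes per region.
#' @param lrr_controls Number of control samples.
#' @param panel_n Individuals in the phased panel.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1,
                            n_probands = 60,
                            trio_fraction = 1.0,
                            fragment_depth = 30,
                            fragment_error = 0.02,
                            haplotype_pool = default_haplotype_pool(),
                            variants = NULL,
                            motif_peak = 0.85,
                            n_training = 2000,
                            flank = 80,
                            exon_length = 62,
                            dosage = dosage_model(100, 0.73, 0.15),
                            expr_n_per_dosage = 20,
                            lrr_shift_het = -0.45,
                            lrr_shift_hom = -2.0,
                            lrr_noise_sd = 0.15,
                            lrr_probes = 4,
                            lrr_controls = 20,
                            panel_n = 2504) {
  if (is.null(variants)) {
    variants <- read_variants(system.file("extdata", "table1_variants.tsv",
                                          package = "cishap"))
  }
  freqs <- vapply(haplotype_pool, `[[`, numeric(1), "frequency")
  if (any(freqs < 0) || sum(freqs) > 1 + 1e-12) {
    stop("haplotype pool frequencies must be non-negative and sum to <= 1")
  }
  members <- unique(unlist(lapply(haplotype_pool, `[[`, "members")))
  unresolved <- setdiff(members, variants$id)
  if (length(unresolved)) {
    stop("pool member(s) not in variant table: ", paste(unresolved, collapse = ", "))
  }
  structure(list(seed = as.integer(seed), n_probands = n_probands,
                 trio_fraction = trio_fraction, fragment_depth = fragment_depth,
                 fragment_error = fragment_error, haplotype_pool = haplotype_pool,
                 variants = variants, motif_peak = motif_peak,
                 n_training = n_training, flank = flank, exon_length = exon_length,
                 dosage = dosage, expr_n_per_dosage = expr_n_per_dosage,
                 lrr_shift_het = lrr_shift_het, lrr_shift_hom = lrr_shift_hom,
                 lrr_noise_sd = lrr_noise_sd, lrr_probes = lrr_probes,
                 lrr_controls = lrr_controls, panel_n = panel_n),
            class = "scenario_config")
}

pool_sites <- function(cfg) {
  ids <- unique(unlist(lapply(cfg$haplotype_pool, `[[`, "members")))
  idx <- match(ids, cfg$variants$id)
  ids[order(cfg$variants$start[idx])]
}

# draw haplotype keys from the pool; include_reference adds the reference
# remainder as key "ref"
draw_haplotypes <- function(cfg, n, include_reference = TRUE) {
  keys <- names(cfg$haplotype_pool)
  p <- vapply(cfg$haplotype_pool, `[[`, numeric(1), "frequency")
  if (include_reference) {
    keys <- c(keys, "ref")
    p <- c(p, 1 - sum(p))
  } else {
    p <- p / sum(p)
  }
  sample(keys, n, replace = TRUE, prob = p)
}

hap_members <- function(cfg, key) {
  if (key == "ref") character() else cfg$haplotype_pool[[key]]$members
}

#' Generate a synthetic cohort with trios, fragments, and phase truth
#'
#' Each proband draws two non-reference haplotypes from the pool (an affected
#' cohort is ascertained for biallelic variant chromosomes); parents are
#' constructed backwards so Mendelian transmission is exact — the father
#' carries the proband's first haplotype plus a population draw, the mother
#' the second. Fragments co-observe every variant pair the proband carries at
#' the configured depth, drawing one of the two chromosomes per fragment and
#' flipping each observation independently with the configured error rate.
#' The truth record stores each proband's drawn haplotypes.
#'
#' @param cfg A [scenario_config()].
#' @return A list with `cohort` (a `cohort` object), `trios` (named list of
#'   [trio()]s for the trio-typed probands), `fragments` (named list of
#'   fragment tables), and `truth` (`data.frame` of drawn haplotype keys).
#' @export
gen_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  sites <- pool_sites(cfg)
  with_seed(derive_seed(cfg$seed, 101L), {
    hap1 <- draw_haplotypes(cfg, cfg$n_probands, include_reference = FALSE)
    hap2 <- draw_haplotypes(cfg, cfg$n_probands, include_reference = FALSE)
    has_trio <- seq_len(cfg$n_probands) <= round(cfg$trio_fraction * cfg$n_probands)
    records <- vector("list", cfg$n_probands)
    trios <- list()
    fragments <- list()
    dosage_of <- function(keys) {
      m1 <- sites %in% hap_members(cfg, keys[1])
      m2 <- sites %in% hap_members(cfg, keys[2])
      setNames(as.integer(m1) + as.integer(m2), sites)
    }
    for (i in seq_len(cfg$n_probands)) {
      pid <- sprintf("P%03d", i)
      origin1 <- if (has_trio[i]) "paternal" else "unknown"
      origin2 <- if (has_trio[i]) "maternal" else "unknown"
      records[[i]] <- proband_record(
        pid, sex = sample(c("M", "F"), 1L),
        allele1 = allele_call(hap_members(cfg, hap1[i]), origin1),
        allele2 = allele_call(hap_members(cfg, hap2[i]), origin2),
        phase_method = if (has_trio[i]) "trios" else "ccs_reads",
        group = "two_VUS")
      pd <- dosage_of(c(hap1[i], hap2[i]))
      if (has_trio[i]) {
        f_other <- draw_haplotypes(cfg, 1L)
        m_other <- draw_haplotypes(cfg, 1L)
        trios[[pid]] <- trio(proband = pd,
                             father = dosage_of(c(hap1[i], f_other)),
                             mother = dosage_of(c(hap2[i], m_other)))
      }
      carried <- sites[pd >= 1L]
      if (length(carried) >= 2L) {
        chrom <- list(setNames(sites %in% hap_members(cfg, hap1[i]), sites),
                      setNames(sites %in% hap_members(cfg, hap2[i]), sites))
        pairs <- combn(carried, 2L, simplify = FALSE)
        rows <- list()
        fid <- 0L
        for (p in pairs) {
          for (k in seq_len(cfg$fragment_depth)) {
            fid <- fid + 1L
            cc <- chrom[[sample(1:2, 1L)]]
            obs <- cc[p]
            flip <- runif(2L) < cfg$fragment_error
            obs <- xor(obs, flip)
            rows[[fid]] <- data.frame(
              fragment_id = sprintf("%s_f%05d", pid, fid),
              variant_id = p, allele = ifelse(obs, "alt", "ref"),
              stringsAsFactors = FALSE)
          }
        }
        fragments[[pid]] <- do.call(rbind, rows)
      }
    }
    cohort <- structure(records, class = "cohort", variants = cfg$variants)
    truth <- data.frame(proband_id = vapply(records, `[[`, character(1), "proband_id"),
                        hap1 = hap1, hap2 = hap2, stringsAsFactors = FALSE)
    list(cohort = cohort, trios = trios, fragments = fragments, truth = truth)
  })
}

#' Generate a phased population panel from the haplotype pool
#'
#' Draws `2 * panel_n` haplotypes i.i.d. from the pool (including the
#' reference remainder) and codes them 0/1 over the pool's site list. The
#' planted frequencies are attached as attribute `"truth"`.
#'
#' @param cfg A [scenario_config()].
#' @return A [phased_panel()].
#' @export
gen_panel <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  sites <- pool_sites(cfg)
  with_seed(derive_seed(cfg$seed, 202L), {
    keys <- draw_haplotypes(cfg, 2L * cfg$panel_n)
    m <- t(vapply(keys, function(k) as.integer(sites %in% hap_members(cfg, k)),
                  integer(length(sites))))
    colnames(m) <- sites
    rownames(m) <- sprintf("hap%05d", seq_along(keys))
    panel <- phased_panel(m)
    attr(panel, "truth") <- c(vapply(cfg$haplotype_pool, `[[`, numeric(1), "frequency"),
                              ref = 1 - sum(vapply(cfg$haplotype_pool, `[[`,
                                                   numeric(1), "frequency")))
    attr(panel, "keys") <- keys
    panel
  })
}

sample_from_table <- function(freq_table, n) {
  # freq_table: positions x 4 matrix of base probabilities
  vapply(seq_len(n), function(i) {
    paste(apply(freq_table, 1L, function(p) sample(DNA_BASES, 1L, prob = p)),
          collapse = "")
  }, character(1))
}

peaked_table <- function(consensus, peak) {
  chars <- strsplit(consensus, "")[[1]]
  t(vapply(chars, function(b) {
    p <- rep((1 - peak) / 3, 4)
    names(p) <- DNA_BASES
    p[b] <- peak
    p
  }, numeric(4)))
}

#' Generate splice-motif training data and reference windows
#'
#' Samples true donor 9-mers and acceptor 23-mers from peaked per-position
#' frequency tables (consensus `CAGGTAAGT` and a pyrimidine-tract acceptor
#' motif), decoys from a uniform background, and builds a synthetic
#' intron–exon–intron locus whose two 162-bp windows overlap across the exon
#' and share an exonic anchor position, mirroring a short internal exon
#' flanked by its acceptor and donor sites.
#'
#' @param cfg A [scenario_config()].
#' @return A list with `donor_sites`, `acceptor_sites`, `decoys`, `windows`
#'   (named list of [splice_window()]s with anchor positions set),
#'   `window_sites` (full-window training sequences peaked at each window's
#'   reference, for [full_window_span()] models), `locus` (the plus-strand
#'   synthetic sequence), and `anchor` (locus coordinate and window indices).
#' @export
gen_splice_training <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  donor_consensus <- "CAGGTAAGT"
  acceptor_consensus <- "CTTTTTTTTTTTTTTTTTAGGTC"
  with_seed(derive_seed(cfg$seed, 303L), {
    donor_tab <- peaked_table(donor_consensus, cfg$motif_peak)
    acc_tab <- peaked_table(acceptor_consensus, cfg$motif_peak)
    donor_sites <- sample_from_table(donor_tab, cfg$n_training)
    acceptor_sites <- sample_from_table(acc_tab, cfg$n_training)
    decoys <- vapply(seq_len(cfg$n_training), function(i) {
      paste(sample(DNA_BASES, 23L, replace = TRUE), collapse = "")
    }, character(1))

    flank <- cfg$flank
    exon_len <- cfg$exon_length
    L <- 2L * flank + 2L  # window length (162 by default)
    locus_len <- flank + 2L + exon_len + 2L + flank
    locus <- sample(DNA_BASES, locus_len, replace = TRUE)
    acc_dinuc <- flank + 1L                  # AG of the acceptor
    don_dinuc <- flank + 2L + exon_len + 1L  # GT of the donor
    # embed the consensus motifs at the two sites
    acc_start <- acc_dinuc - 18L
    locus[acc_start:(acc_start + 22L)] <- strsplit(acceptor_consensus, "")[[1]]
    don_start <- don_dinuc - 3L
    locus[don_start:(don_start + 8L)] <- strsplit(donor_consensus, "")[[1]]
    anchor_locus <- acc_dinuc + 2L + exon_len %/% 2L  # mid-exon
    # pin the anchor's reference base (a G>A anchor, like the synonymous
    # exon-10 allele) so the alternative allele is always a real substitution
    locus[anchor_locus] <- "G"
    locus <- paste(locus, collapse = "")
    donor_window_start <- don_dinuc - flank
    windows <- list(
      acceptor_3ss = window_from_genome(locus, 1L, L, "+", "acceptor_3ss",
                                        dinucleotide_start = acc_dinuc,
                                        anchor_position = anchor_locus,
                                        contig = "synthetic_locus"),
      donor_5ss = window_from_genome(locus, donor_window_start,
                                     donor_window_start + L - 1L, "+", "donor_5ss",
                                     dinucleotide_start = flank + 1L,
                                     anchor_position = anchor_locus - donor_window_start + 1L,
                                     contig = "synthetic_locus")
    )
    # full-window training sets: sequences peaked at each window's reference,
    # for models that score the whole 162-bp window (full_window_span)
    n_full <- max(100L, cfg$n_training %/% 4L)
    window_sites <- lapply(windows, function(w) {
      sample_from_table(peaked_table(paste(w$sequence, collapse = ""),
                                     cfg$motif_peak), n_full)
    })
    list(donor_sites = donor_sites, acceptor_sites = acceptor_sites,
         decoys = decoys, windows = windows, window_sites = window_sites,
         locus = locus,
         anchor = list(locus_position = anchor_locus,
                       acceptor_index = anchor_locus,
                       donor_index = anchor_locus - donor_window_start + 1L))
  })
}

#' Generate synthetic expression samples under the scenario's dosage model
#'
#' @param cfg A [scenario_config()].
#' @return A `data.frame` from [simulate_expression()] with
#'   `expr_n_per_dosage` samples at each dosage 0, 1, 2.
#' @export
gen_expression <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  dosages <- rep(0:2, each = cfg$expr_n_per_dosage)
  simulate_expression(cfg$dosage, dosages, seed = derive_seed(cfg$seed, 404L))
}

#' Generate synthetic LRR tables with planted copy-number states
#'
#' Controls are diploid samples with zero mean shift; test samples carry the
#' planted copy-number states (2 = no shift, 1 = `lrr_shift_het`, 0 =
#' `lrr_shift_hom`), all with Gaussian probe noise.
#'
#' @param cfg A [scenario_config()].
#' @param cn_states Integer vector of planted copy numbers, one test sample
#'   each.
#' @param region Region label for all probes.
#' @return A list with `samples`, `controls` (LRR `data.frame`s) and `truth`.
#' @export
gen_lrr <- function(cfg, cn_states = c(2L, 1L, 0L), region = "exon14") {
  stopifnot(inherits(cfg, "scenario_config"), all(cn_states %in% 0:2))
  with_seed(derive_seed(cfg$seed, 505L), {
    make_obs <- function(sample_id, shift) {
      data.frame(sample_id = sample_id,
                 probe_id = sprintf("probe%02d", seq_len(cfg$lrr_probes)),
                 region = region,
                 lrr = shift + rnorm(cfg$lrr_probes, 0, cfg$lrr_noise_sd),
                 stringsAsFactors = FALSE)
    }
    controls <- do.call(rbind, lapply(seq_len(cfg$lrr_controls), function(i) {
      make_obs(sprintf("ctrl%03d", i), 0)
    }))
    shifts <- c(`2` = 0, `1` = cfg$lrr_shift_het, `0` = cfg$lrr_shift_hom)
    samples <- do.call(rbind, lapply(seq_along(cn_states), function(i) {
      make_obs(sprintf("case%03d", i), shifts[[as.character(cn_states[i])]])
    }))
    truth <- data.frame(sample_id = sprintf("case%03d", seq_along(cn_states)),
                        copy_number = as.integer(cn_states),
                        stringsAsFactors = FALSE)
    list(samples = samples, controls = controls, truth = truth)
  })
}
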