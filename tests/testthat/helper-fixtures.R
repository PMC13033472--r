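# shared fixture accessors and independent oracles used across test files

fixture_variants <- function() {
  read_variants(system.file("extdata", "table1_variants.tsv", package = "cishap"))
}

fixture_cohort <- function() {
  read_cohort(system.file("extdata", "table1_cohort.tsv", package = "cishap"),
              fixture_variants())
}

# ---- independent oracles (deliberately written as direct enumerations, ----
# ---- not reusing package internals)                                    ----

# point-in-interval containment of a 0-based point in half-open intervals
oracle_in_repeat <- function(contig, point0, repeats) {
  hit <- FALSE
  for (i in seq_len(nrow(repeats))) {
    if (repeats$contig[i] == contig &&
        point0 >= repeats$start[i] && point0 < repeats$end[i]) {
      hit <- TRUE
    }
  }
  hit
}

# brute-force trio phase: enumerate all parental haplotype allele assignments
# (four alleles per parent) and all four transmissions; relation over the
# surviving configurations
oracle_phase_trio <- function(dp, df, dm) {
  relations <- character()
  for (fa1 in 0:1) for (fb1 in 0:1) for (fa2 in 0:1) for (fb2 in 0:1) {
    if (!is.na(df[1]) && fa1 + fa2 != df[1]) next
    if (!is.na(df[2]) && fb1 + fb2 != df[2]) next
    for (ma1 in 0:1) for (mb1 in 0:1) for (ma2 in 0:1) for (mb2 in 0:1) {
      if (!is.na(dm[1]) && ma1 + ma2 != dm[1]) next
      if (!is.na(dm[2]) && mb1 + mb2 != dm[2]) next
      for (tf in 1:2) for (tm in 1:2) {
        pa <- if (tf == 1) c(fa1, fb1) else c(fa2, fb2)
        mo <- if (tm == 1) c(ma1, mb1) else c(ma2, mb2)
        if (pa[1] + mo[1] != dp[1] || pa[2] + mo[2] != dp[2]) next
        cis <- (pa[1] == 1 && pa[2] == 1) || (mo[1] == 1 && mo[2] == 1)
        relations <- c(relations, if (cis) "cis" else "trans")
      }
    }
  }
  if (!length(relations)) return("mendelian_error")
  u <- unique(relations)
  if (length(u) == 1L) u else "ambiguous"
}

# direct full rescoring of a WMM over an edited window (independent of the
# package's scoring path)
oracle_wmm_score <- function(freqs, background, motif_chars) {
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (p in seq_along(motif_chars)) {
    b <- match(motif_chars[p], bases)
    s <- s + log2(freqs[p, b] / background[b])
  }
  s
}

# random splice window with given length and site type
random_window <- function(L, site_type, anchor_position = NULL) {
  d <- (L - 2L) %/% 2L + 1L
  chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  chars[d:(d + 1L)] <- if (site_type == "donor_5ss") c("G", "T") else c("A", "G")
  splice_window(paste(chars, collapse = ""), site_type,
                dinucleotide_start = d, anchor_position = anchor_position)
}

# run the full synthetic phasing pipeline for a generated cohort
phase_generated_cohort <- function(gen) {
  calls <- lapply(gen$cohort, function(r) {
    resolve_proband(r, gen$trios[[r$proband_id]], gen$fragments[[r$proband_id]])
  })
  names(calls) <- vapply(gen$cohort, `[[`, character(1), "proband_id")
  calls
}
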