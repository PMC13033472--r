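test_that("variant labels normalize typographic variation", {
  expect_equal(normalize_variant_label("c.2310 T>G"), "c.2310T>G")
  expect_equal(normalize_variant_label("c.2433‐22,889 T>A"), "c.2433-22889T>A")
  expect_equal(normalize_variant_label("143 kb/184 kb CxSV"), "cxsv_143kb_184kb_del")
  expect_equal(normalize_variant_label("143 kb inverted dup CxSV"), "cxsv_143kb_invdup")
  # semicolons inside brackets are one symbolic SV, not a cis separator
  expect_equal(
    split_cis("c.79G>A; g.[27975445_27984368dup;27984368_27984369insTTAACA]")[[1]],
    c("c.79G>A", "g.[27975445_27984368dup;27984368_27984369insTTAACA]"))
})

test_that("the packaged cohort parses into one record per proband", {
  cohort <- fixture_cohort()
  expect_length(cohort, 106)
  # homozygote for the recurring two-variant cis allele
  r1252 <- cohort[[which(vapply(cohort, `[[`, character(1), "proband_id") == "1252")]]
  expect_equal(r1252$allele1$variants, c("c.79G>A", "c.1320G>C"))
  expect_equal(r1252$allele1$variants, r1252$allele2$variants)
  expect_equal(r1252$allele1$parental_origin, "paternal")
})

test_that("an empty cohort body yields an empty record list", {
  tmp <- tempfile()
  writeLines(paste("proband_id", "sex", "variant1", "origin1", "variant2",
                   "origin2", "phase_method", "group", sep = "\t"), tmp)
  expect_length(read_cohort(tmp, fixture_variants()), 0)
})

test_that("unresolvable labels and duplicate probands are hard errors", {
  v <- fixture_variants()
  tmp <- tempfile()
  header <- paste("proband_id", "sex", "variant1", "origin1", "variant2",
                  "origin2", "phase_method", "group", sep = "\t")
  writeLines(c(header,
               paste("p1", "F", "c.9999X>Y", "", "c.79G>A", "", "trios", "two_VUS",
                     sep = "\t")), tmp)
  expect_error(read_cohort(tmp, v), "c\\.9999X>Y")
  row <- paste("p1", "F", "c.79G>A", "", "c.79G>A", "", "trios", "two_VUS", sep = "\t")
  writeLines(c(header, row, row), tmp)
  expect_error(read_cohort(tmp, v), "duplicate proband")
})

test_that("reading then writing the cohort reproduces the table byte-identically", {
  src <- system.file("extdata", "table1_cohort.tsv", package = "cishap")
  tmp <- tempfile()
  write_cohort(read_cohort(src, fixture_variants()), tmp)
  expect_identical(readLines(tmp), readLines(src))
})

test_that("rarity classification is strict at the threshold and honest about missing MAFs", {
  expect_equal(classify_rarity(0.05792), "common")
  expect_equal(classify_rarity(0.01), "common")   # strict '<'
  expect_equal(classify_rarity(0.0011), "rare")
  expect_equal(classify_rarity(NA_real_), "unknown")
  expect_equal(classify_rarity(c(0.5, 0.001, NA)), c("common", "rare", "unknown"))
})

test_that("allele counts match the published cohort tallies", {
  cohort <- fixture_cohort()
  expect_equal(allele_count(cohort, "c.1327G>A"), 37)
  expect_equal(allele_count(cohort, "c.1465A>G"), 13)
  expect_equal(allele_count(cohort, "c.2228C>T"), 11)
  expect_equal(allele_count(cohort, "c.1320G>C"), 8)
  expect_equal(allele_count(cohort, "g.28017719_28020678delinsTTT"), 29)
  expect_equal(allele_count(cohort, "g.27979571_27984604del"), 7)
  expect_equal(allele_count(cohort, "absent_variant"), 0)
})

test_that("distinct counts: member-wise ids, allele units, and class tallies agree", {
  cohort <- fixture_cohort()
  dv <- distinct_variants(cohort)
  # the printed table holds 75 member ids; the published total of 74 counts
  # the recurring cis pair as one allele unit
  expect_length(dv, 75)
  expect_length(distinct_alleles(cohort), 74)
  by_class <- attr(dv, "by_class")
  expect_equal(sum(by_class), length(dv))
  expect_equal(sum(by_class[c("sv_deletion", "sv_duplication", "cxsv")]), 11)
  expect_equal(unname(by_class["missense"]), 35)
  # allele-unit classes fold the all-missense pair into missense: total 34
  da_class <- attr(distinct_alleles(cohort), "by_class")
  expect_equal(unname(da_class["missense"]), 34)
})

test_that("total allele occurrences equal summed allele-call sizes", {
  cohort <- fixture_cohort()
  ids <- as.character(distinct_variants(cohort))
  total <- sum(vapply(ids, function(id) allele_count(cohort, id), integer(1)))
  slots <- sum(vapply(cohort, function(r) {
    length(r$allele1$variants) + length(r$allele2$variants)
  }, integer(1)))
  expect_equal(total, slots)
})

test_that("SV carrier counting is per proband, idempotent over multiple SVs", {
  cohort <- fixture_cohort()
  expect_equal(sv_carrier_count(cohort), 41)
  v <- fixture_variants()
  no_sv <- structure(cohort[vapply(cohort, function(r) {
    !any(carried <- c(r$allele1$variants, r$allele2$variants) %in%
           v$id[v$vclass %in% c("sv_deletion", "sv_duplication", "cxsv")])
  }, logical(1))], class = "cohort", variants = v)
  expect_equal(sv_carrier_count(no_sv), 0)
  # two SV alleles in one proband count once (e.g. proband 3289, homozygous)
  one <- structure(cohort[vapply(cohort, `[[`, character(1), "proband_id") == "3289"],
                   class = "cohort", variants = v)
  expect_equal(sv_carrier_count(one), 1)
})

test_that("junction endpoints use the half-open BED convention", {
  reps <- repeat_track("chr1", start = 100, end = 200, repeat_class = "LINE")
  inside <- variant("sv_in", "sv_deletion", contig = "chr1", start = 150, end = 400)
  ann <- annotate_junctions(inside, reps)
  expect_true(ann$start_in_repeat)   # left junction at 0-based 149, inside
  expect_false(ann$end_in_repeat)
  # right junction exactly at the BED end coordinate is not flagged
  at_end <- variant("sv_end", "sv_deletion", contig = "chr1", start = 50, end = 200)
  ann2 <- annotate_junctions(at_end, reps)
  expect_false(ann2$end_in_repeat)
  expect_false(ann2$start_in_repeat) # 0-based 49 < 100
  # contig mismatch warns and flags nothing
  off <- variant("sv_off", "sv_deletion", contig = "chr2", start = 150, end = 160)
  expect_warning(ann3 <- annotate_junctions(off, reps), "contig")
  expect_false(ann3$start_in_repeat)
})

test_that("junction annotation agrees with an exhaustive containment oracle", {
  withr::with_seed(42, {
    for (rep_i in 1:5) {
      n_sv <- 12
      svs <- do.call(rbind, lapply(seq_len(n_sv), function(i) {
        s <- sample(1:1000, 1)
        variant(paste0("sv", i), "sv_deletion", contig = sample(c("c1", "c2"), 1),
                start = s, end = s + sample(1:500, 1))
      }))
      class(svs) <- c("variant_table", "data.frame")
      starts <- sample(1:1200, 15)
      reps <- repeat_track(sample(c("c1", "c2"), 15, replace = TRUE),
                           starts, starts + sample(1:100, 15, replace = TRUE),
                           sample(c("LINE", "SINE", "LTR"), 15, replace = TRUE))
      ann <- suppressWarnings(annotate_junctions(svs, reps))
      for (i in seq_len(n_sv)) {
        expect_equal(ann$start_in_repeat[i],
                     oracle_in_repeat(svs$contig[i], svs$start[i] - 1, reps))
        expect_equal(ann$end_in_repeat[i],
                     oracle_in_repeat(svs$contig[i], svs$end[i], reps))
      }
    }
  })
})

test_that("fixture SV junctions land in the packaged synthetic repeat track", {
  reps <- read_repeats(system.file("extdata", "synthetic_repeats.bed",
                                   package = "cishap"))
  v <- fixture_variants()
  ann <- annotate_junctions(v, reps)
  expect_equal(nrow(ann), 11)
  expect_true(any(ann$start_in_repeat | ann$end_in_repeat))
})
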