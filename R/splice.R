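DNA_BASES <- c("A", "C", "G", "T")

#' Construct a splice window
#'
#' A reference sequence window around one splice site, held in transcript
#' orientation: for a donor (5'SS) the exon is on the left and the consensus
#' `GT` dinucleotide starts the intron; for an acceptor (3'SS) the intron is
#' on the left and ends with `AG`. The default geometry is 80 bp of flank on
#' each side of the dinucleotide (window length 162).
#'
#' @param sequence DNA string (character or `Biostrings::DNAString`) in
#'   transcript orientation.
#' @param site_type `"donor_5ss"` or `"acceptor_3ss"`.
#' @param dinucleotide_start 1-based window index of the first consensus
#'   dinucleotide base; defaults to the centered position `(L - 2) / 2 + 1`.
#' @param anchor_position Optional window index of the anchor allele.
#' @param genome_map Optional `data.frame` with columns `window_position`,
#'   `contig`, `genomic_position`, `strand` mapping window indices to the
#'   reference genome.
#' @return An object of class `splice_window`.
#' @export
splice_window <- function(sequence, site_type,
                          dinucleotide_start = NULL, anchor_position = NULL,
                          genome_map = NULL) {
  site_type <- match.arg(site_type, c("donor_5ss", "acceptor_3ss"))
  seq <- toupper(as.character(sequence))
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  if (L < 3L) stop("splice window too short")
  if (is.null(dinucleotide_start)) dinucleotide_start <- (L - 2L) %/% 2L + 1L
  dinuc <- paste0(chars[dinucleotide_start], chars[dinucleotide_start + 1L])
  expected <- if (site_type == "donor_5ss") "GT" else "AG"
  if (dinuc != expected) {
    stop(sprintf("reference dinucleotide at positions %d-%d is %s, expected %s",
                 dinucleotide_start, dinucleotide_start + 1L, dinuc, expected))
  }
  if (!is.null(anchor_position)) {
    if (anchor_position %in% c(dinucleotide_start, dinucleotide_start + 1L)) {
      stop("anchor position cannot sit on the consensus dinucleotide")
    }
    if (anchor_position < 1L || anchor_position > L) stop("anchor position outside window")
  }
  structure(list(sequence = chars, site_type = site_type, length = L,
                 dinucleotide_start = as.integer(dinucleotide_start),
                 anchor_position = if (is.null(anchor_position)) NULL else as.integer(anchor_position),
                 genome_map = genome_map),
            class = "splice_window")
}

#' Build a splice window from plus-strand genomic sequence
#'
#' Extracts `[start, end]` (1-based inclusive) from a plus-strand reference
#' sequence and reverse-complements when the transcript is on the minus
#' strand, so the window is always in transcript orientation. The genome map
#' records, for every window index, the plus-strand genomic coordinate it came
#' from.
#'
#' @param reference Plus-strand reference sequence (character,
#'   `Biostrings::DNAString`, or a path to a FASTA file whose first record is
#'   used).
#' @param start,end 1-based inclusive coordinates of the window on the plus
#'   strand.
#' @param strand `"+"` or `"-"` (transcript strand).
#' @param site_type,dinucleotide_start,anchor_position See [splice_window()];
#'   indices refer to the transcript-oriented window.
#' @param contig Contig name recorded in the genome map.
#' @return A [splice_window()].
#' @export
window_from_genome <- function(reference, start, end, strand, site_type,
                               dinucleotide_start = NULL, anchor_position = NULL,
                               contig = "chr15") {
  if (is.character(reference) && length(reference) == 1L && file.exists(reference)) {
    reference <- as.character(Biostrings::readDNAStringSet(reference)[[1]])
  }
  ref <- Biostrings::DNAString(as.character(reference))
  stopifnot(start >= 1L, end <= length(ref), start <= end)
  sub <- Biostrings::subseq(ref, start, end)
  if (strand == "-") sub <- Biostrings::reverseComplement(sub)
  L <- end - start + 1L
  genomic <- if (strand == "+") start:end else end:start
  gm <- data.frame(window_position = seq_len(L), contig = contig,
                   genomic_position = genomic, strand = strand,
                   stringsAsFactors = FALSE)
  splice_window(as.character(sub), site_type,
                dinucleotide_start = dinucleotide_start,
                anchor_position = anchor_position, genome_map = gm)
}

#' Construct a haplotype edit (window substitutions)
#'
#' @param pos Integer vector of 1-based window positions (distinct).
#' @param alt Character vector of alternative bases.
#' @return A `data.frame` with columns `pos`, `alt`.
#' @export
haplotype_edit <- function(pos, alt) {
  if (anyDuplicated(pos)) stop("edit positions must be distinct")
  alt <- toupper(alt)
  if (!all(alt %in% DNA_BASES)) stop("alt bases must be A/C/G/T")
  data.frame(pos = as.integer(pos), alt = alt, stringsAsFactors = FALSE)
}

#' Apply edits to a splice window sequence
#'
#' @param w A [splice_window()].
#' @param edits A [haplotype_edit()] `data.frame` (or `NULL` for the
#'   reference). Each alt must differ from the reference base at its position.
#' @return Character vector of window bases after substitution.
#' @export
apply_edits <- function(w, edits = NULL) {
  chars <- w$sequence
  if (is.null(edits) || !nrow(edits)) return(chars)
  if (anyDuplicated(edits$pos)) stop("edit positions must be distinct")
  if (any(edits$pos < 1L | edits$pos > w$length)) stop("edit position outside window")
  same <- chars[edits$pos] == edits$alt
  if (any(same)) {
    stop("edit(s) identical to the reference base at position(s) ",
         paste(edits$pos[same], collapse = ", "))
  }
  chars[edits$pos] <- edits$alt
  chars
}

default_span <- function(site_type) {
  if (site_type == "donor_5ss") c(exonic = 3L, intronic = 6L)
  else c(exonic = 3L, intronic = 20L)
}

#' Motif span covering a whole splice window
#'
#' Models trained with this span score every window position (the
#' 80-bp-flank windowed-scoring approach), so substitutions anywhere in the
#' flanks — including a shared exonic anchor — contribute to the score.
#'
#' @param w A [splice_window()].
#' @return Named vector `c(exonic=, intronic=)` spanning the full window.
#' @export
full_window_span <- function(w) {
  d <- w$dinucleotide_start
  if (w$site_type == "donor_5ss") {
    c(exonic = d - 1L, intronic = w$length - d + 1L)
  } else {
    c(exonic = w$length - d - 1L, intronic = d + 1L)
  }
}

#' Train a splice-site scorer from aligned true sites and decoys
#'
#' Two pluggable motif models are provided. The weight-matrix model (`wmm`)
#' stores per-position log2 odds of pseudocounted position frequencies over a
#' decoy-derived background. The weight-array model (`wam`) adds first-order
#' dependence: positions beyond the first are scored by their frequency
#' conditional on the preceding base. Pseudocounts are distributed by the
#' background composition: `f = (n_b + pc * q_b) / (n + pc)`.
#'
#' @param true_sites Character vector of aligned true-site sequences, all of
#'   one length equal to the motif span (donor 9-mer: 3 exonic + GT + 4
#'   intronic; acceptor 23-mer: 18 intronic + AG + 3 exonic).
#' @param decoys Character vector of background sequences (any lengths); their
#'   pooled base composition is the background. `NULL` gives a uniform
#'   background.
#' @param model_type `"wmm"` or `"wam"`.
#' @param site_type `"donor_5ss"` or `"acceptor_3ss"`.
#' @param pseudocount Positive pseudocount mass (default 1, Laplace-style).
#' @param span Named vector `c(exonic=, intronic=)` placing the motif around
#'   the consensus dinucleotide; defaults to donor (3, 6) / acceptor (3, 20).
#' @return An object of class `scorer_model`.
#' @export
train_scorer <- function(true_sites, decoys = NULL,
                         model_type = c("wmm", "wam"),
                         site_type = c("donor_5ss", "acceptor_3ss"),
                         pseudocount = 1, span = NULL) {
  model_type <- match.arg(model_type)
  site_type <- match.arg(site_type)
  if (!length(true_sites)) stop("at least one true-site sequence is required")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  true_sites <- toupper(true_sites)
  len <- unique(nchar(true_sites))
  if (length(len) != 1L) stop("true-site sequences must share one length")
  span <- span %||% default_span(site_type)
  if (sum(span) != len) {
    stop(sprintf("motif span (%d exonic + %d intronic) does not match sequence length %d",
                 span["exonic"], span["intronic"], len))
  }
  mat <- do.call(rbind, strsplit(true_sites, ""))
  if (!all(mat %in% DNA_BASES)) stop("true sites must be A/C/G/T only")
  n <- nrow(mat)

  background <- if (is.null(decoys)) {
    setNames(rep(0.25, 4), DNA_BASES)
  } else {
    chars <- unlist(strsplit(toupper(decoys), ""))
    cnt <- table(factor(chars, levels = DNA_BASES))
    as.numeric((cnt + pseudocount) / (sum(cnt) + 4 * pseudocount)) |>
      setNames(DNA_BASES)
  }

  freq_at <- function(counts, total) (counts + pseudocount * background) /
    (total + pseudocount)

  if (model_type == "wmm") {
    freqs <- t(vapply(seq_len(len), function(p) {
      cnt <- table(factor(mat[, p], levels = DNA_BASES))
      freq_at(as.numeric(cnt) |> setNames(DNA_BASES), n)
    }, numeric(4)))
    logodds <- log2(sweep(freqs, 2, background, "/"))
    params <- list(freqs = freqs, logodds = logodds)
  } else {
    cnt1 <- table(factor(mat[, 1], levels = DNA_BASES))
    marginal <- freq_at(as.numeric(cnt1) |> setNames(DNA_BASES), n)
    conditional <- lapply(2:len, function(p) {
      t(vapply(DNA_BASES, function(prev) {
        sel <- mat[, p - 1] == prev
        cnt <- table(factor(mat[sel, p], levels = DNA_BASES))
        freq_at(as.numeric(cnt) |> setNames(DNA_BASES), sum(sel))
      }, numeric(4)))
    })
    params <- list(marginal = marginal, conditional = conditional)
  }
  structure(list(model_type = model_type, site_type = site_type,
                 span = span, motif_length = len, background = background,
                 pseudocount = pseudocount, params = params),
            class = "scorer_model")
}

# 1-based window indices covered by the model's motif span
motif_positions <- function(model, w) {
  d <- w$dinucleotide_start
  span <- model$span
  start <- if (model$site_type == "donor_5ss") {
    d - span[["exonic"]]
  } else {
    d - (span[["intronic"]] - 2L)
  }
  idx <- start:(start + model$motif_length - 1L)
  if (any(idx < 1L) || any(idx > w$length)) {
    stop("motif span extends outside the window")
  }
  idx
}

#' Score a splice window under a trained model
#'
#' Applies the edits to the reference window, extracts the model's motif span
#' around the consensus dinucleotide, and returns the summed log2 odds of the
#' motif versus background. Higher scores mean a stronger predicted splice
#' site. Edits at the dinucleotide positions are allowed: destroying the
#' consensus is reflected in the score.
#'
#' @param model A [train_scorer()] model whose `site_type` matches the window.
#' @param w A [splice_window()].
#' @param edits Optional [haplotype_edit()] substitutions.
#' @return Numeric score (log2 odds).
#' @export
splice_score <- function(model, w, edits = NULL) {
  stopifnot(inherits(model, "scorer_model"), inherits(w, "splice_window"))
  if (model$site_type != w$site_type) {
    stop("model and window disagree on site type")
  }
  chars <- apply_edits(w, edits)
  motif <- chars[motif_positions(model, w)]
  base_idx <- match(motif, DNA_BASES)
  if (anyNA(base_idx)) stop("non-ACGT base in motif span")
  if (model$model_type == "wmm") {
    sum(model$params$logodds[cbind(seq_along(motif), base_idx)])
  } else {
    s <- log2(model$params$marginal[base_idx[1]] / model$background[base_idx[1]])
    for (p in 2:length(motif)) {
      f <- model$params$conditional[[p - 1L]][base_idx[p - 1L], base_idx[p]]
      s <- s + log2(f / model$background[base_idx[p]])
    }
    unname(s)
  }
}

#' Compound cis-impact of a variant together with an anchor allele
#'
#' The variant's solo impact is the score change it causes relative to the
#' reference window; the haplotype impact is the score change when the variant
#' and the anchor allele are present together, again relative to the
#' reference.
#'
#' @param model A [train_scorer()] model.
#' @param w A [splice_window()].
#' @param variant,anchor Single-substitution [haplotype_edit()]s at distinct
#'   positions.
#' @return List with `delta_variant`, `delta_haplotype`, and `reference_score`.
#' @export
compound_impact <- function(model, w, variant, anchor) {
  stopifnot(nrow(variant) == 1L, nrow(anchor) == 1L)
  if (variant$pos == anchor$pos) stop("variant and anchor positions must differ")
  ref <- splice_score(model, w)
  list(delta_variant = splice_score(model, w, variant) - ref,
       delta_haplotype = splice_score(model, w, rbind(variant, anchor)) - ref,
       reference_score = ref)
}

#' Report a variant's impact on the strongest affected splice site
#'
#' When a variant position falls inside more than one splice window, only its
#' impact on the site with the larger reference score is reported. Exact
#' reference-score ties break deterministically towards the acceptor.
#'
#' @param models Named list of [train_scorer()] models (names are site types).
#' @param windows Named list of [splice_window()]s (same names).
#' @param edits_by_site Named list of [haplotype_edit()]s giving the variant's
#'   window coordinates in each affected window; sites where the variant does
#'   not map are omitted.
#' @return List with `site_type`, `impact` (score with edits minus reference
#'   at the selected site), and `reference_scores`.
#' @export
strongest_site <- function(models, windows, edits_by_site) {
  sites <- names(edits_by_site)
  if (!length(sites)) stop("the variant must map into at least one window")
  stopifnot(all(sites %in% names(models)), all(sites %in% names(windows)))
  ref <- vapply(sites, function(s) splice_score(models[[s]], windows[[s]]), numeric(1))
  best <- max(ref)
  candidates <- sites[ref == best]
  chosen <- if ("acceptor_3ss" %in% candidates) "acceptor_3ss" else candidates[1]
  impact <- splice_score(models[[chosen]], windows[[chosen]],
                         edits_by_site[[chosen]]) - ref[chosen]
  list(site_type = chosen, impact = unname(impact), reference_scores = ref)
}

#' Serialize a scorer model to a plain-text file
#'
#' The format is line-oriented: `key<TAB>value` header lines (`model_type`,
#' `site_type`, `exonic`, `intronic`, `pseudocount`), a `[background]` block,
#' then `[wmm]` position rows, or `[marginal]` plus one `[conditional <p>]`
#' 4x4 block per position for a weight-array model. Frequencies are written
#' with full precision so read/write round-trips exactly.
#'
#' @param model A [train_scorer()] model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scorer_model <- function(model, path) {
  num <- function(x) format(x, digits = 17, scientific = TRUE)
  lines <- c(
    paste0("model_type\t", model$model_type),
    paste0("site_type\t", model$site_type),
    paste0("exonic\t", model$span[["exonic"]]),
    paste0("intronic\t", model$span[["intronic"]]),
    paste0("pseudocount\t", num(model$pseudocount)),
    "[background]",
    paste(DNA_BASES, num(model$background), sep = "\t")
  )
  if (model$model_type == "wmm") {
    lines <- c(lines, "[wmm]")
    for (p in seq_len(model$motif_length)) {
      lines <- c(lines, paste(c(p, num(model$params$freqs[p, ])), collapse = "\t"))
    }
  } else {
    lines <- c(lines, "[marginal]",
               paste(num(model$params$marginal), collapse = "\t"))
    for (p in seq_along(model$params$conditional)) {
      lines <- c(lines, paste0("[conditional ", p + 1L, "]"))
      m <- model$params$conditional[[p]]
      for (prev in DNA_BASES) {
        lines <- c(lines, paste(c(prev, num(m[prev, ])), collapse = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a scorer model written by [write_scorer_model()]
#'
#' @param path Path to the model file.
#' @return A `scorer_model`.
#' @export
read_scorer_model <- function(path) {
  lines <- readLines(path)
  kv <- function(key) {
    ln <- grep(paste0("^", key, "\t"), lines, value = TRUE)[1]
    strsplit(ln, "\t")[[1]][2]
  }
  model_type <- kv("model_type")
  site_type <- kv("site_type")
  span <- c(exonic = as.integer(kv("exonic")), intronic = as.integer(kv("intronic")))
  pseudocount <- as.numeric(kv("pseudocount"))
  blk <- function(tag) which(lines == tag)
  bg_rows <- lines[(blk("[background]") + 1):(blk("[background]") + 4)]
  background <- setNames(
    vapply(strsplit(bg_rows, "\t"), function(x) as.numeric(x[2]), numeric(1)),
    vapply(strsplit(bg_rows, "\t"), `[`, character(1), 1))
  len <- sum(span)
  if (model_type == "wmm") {
    start <- blk("[wmm]")
    freqs <- do.call(rbind, lapply(lines[(start + 1):(start + len)], function(ln) {
      as.numeric(strsplit(ln, "\t")[[1]][-1])
    }))
    colnames(freqs) <- DNA_BASES
    params <- list(freqs = freqs,
                   logodds = log2(sweep(freqs, 2, background[DNA_BASES], "/")))
  } else {
    start <- blk("[marginal]")
    marginal <- setNames(as.numeric(strsplit(lines[start + 1], "\t")[[1]]), DNA_BASES)
    conditional <- lapply(2:len, function(p) {
      s <- blk(paste0("[conditional ", p, "]"))
      m <- do.call(rbind, lapply(lines[(s + 1):(s + 4)], function(ln) {
        as.numeric(strsplit(ln, "\t")[[1]][-1])
      }))
      dimnames(m) <- list(DNA_BASES, DNA_BASES)
      m
    })
    params <- list(marginal = marginal, conditional = conditional)
  }
  structure(list(model_type = model_type, site_type = site_type, span = span,
                 motif_length = len, background = background[DNA_BASES],
                 pseudocount = pseudocount, params = params),
            class = "scorer_model")
}
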