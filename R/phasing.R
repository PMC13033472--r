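#' Construct a trio of site genotypes
#'
#' Genotypes are alt-allele dosages in `{0, 1, 2}` per variant site; `NA`
#' marks a missing call. All three members must be typed over the same site
#' set (missing values allowed).
#'
#' @param proband,father,mother Named integer vectors of dosages (names are
#'   variant ids).
#' @return An object of class `trio`.
#' @export
trio <- function(proband, father, mother) {
  sites <- names(proband)
  if (is.null(sites) || !setequal(sites, names(father)) ||
      !setequal(sites, names(mother))) {
    stop("proband, father and mother must be typed over the same variant ids")
  }
  check <- function(g) {
    if (any(!is.na(g) & !(g %in% 0:2))) stop("dosages must be 0, 1, 2 or NA")
    g
  }
  structure(list(proband = check(proband), father = check(father)[sites],
                 mother = check(mother)[sites]),
            class = "trio")
}

# all (hap1, hap2) allele assignments at two sites compatible with a pair of
# dosages; NA dosage is unconstrained. Rows: h1_a, h1_b, h2_a, h2_b.
parent_configs <- function(da, db) {
  grid <- expand.grid(h1_a = 0:1, h1_b = 0:1, h2_a = 0:1, h2_b = 0:1)
  keep <- rep(TRUE, nrow(grid))
  if (!is.na(da)) keep <- keep & (grid$h1_a + grid$h2_a == da)
  if (!is.na(db)) keep <- keep & (grid$h1_b + grid$h2_b == db)
  grid[keep, , drop = FALSE]
}

#' Resolve cis/trans phase of a variant pair by trio segregation
#'
#' Enumerates every assignment of parental haplotypes and transmissions
#' consistent with all six genotypes, assuming no recombination between the
#' two sites (they lie within one gene locus). The relation is `cis` when
#' every consistent assignment places the proband's alt alleles at both sites
#' on the same transmitted haplotype, `trans` when they are always on opposite
#' haplotypes, `ambiguous` when both configurations survive, and
#' `mendelian_error` when no assignment is consistent (including de novo
#' alleles absent from both parents). Missing parental genotypes are
#' unconstrained and naturally degrade the call towards `ambiguous` unless the
#' proband's homozygosity forces the relation.
#'
#' @param t A [trio()].
#' @param a,b Variant ids; the proband must carry at least one alt allele at
#'   each.
#' @return A `phase_call`: list with `pair`, `relation`, `origin` (named
#'   vector over `a`/`b` with values `"paternal"`/`"maternal"` where unique),
#'   and `support` (number of consistent transmission configurations).
#' @examples
#' # father carries a only, mother carries b only: the pair is in trans
#' t <- trio(proband = c(a = 1, b = 1), father = c(a = 1, b = 0),
#'           mother = c(a = 0, b = 1))
#' phase_trio(t, "a", "b")$relation
#' @export
phase_trio <- function(t, a, b) {
  stopifnot(inherits(t, "trio"))
  dp <- t$proband[c(a, b)]
  if (any(is.na(dp)) || any(dp < 1)) {
    stop("phase_trio needs proband dosage >= 1 at both sites")
  }
  fconf <- parent_configs(t$father[a], t$father[b])
  mconf <- parent_configs(t$mother[a], t$mother[b])
  relations <- character()
  origins_a <- character()
  origins_b <- character()
  support <- 0L
  for (fi in seq_len(nrow(fconf))) for (mi in seq_len(nrow(mconf))) {
    for (tf in 1:2) for (tm in 1:2) {
      pat <- c(fconf[fi, c("h1_a", "h1_b")], fconf[fi, c("h2_a", "h2_b")])[
        if (tf == 1) 1:2 else 3:4]
      mat <- c(mconf[mi, c("h1_a", "h1_b")], mconf[mi, c("h2_a", "h2_b")])[
        if (tm == 1) 1:2 else 3:4]
      pat <- as.integer(pat); mat <- as.integer(mat)
      if (pat[1] + mat[1] != dp[1] || pat[2] + mat[2] != dp[2]) next
      support <- support + 1L
      # cis when some transmitted haplotype carries alt at both sites
      cis_here <- (pat[1] == 1 && pat[2] == 1) || (mat[1] == 1 && mat[2] == 1)
      relations <- c(relations, if (cis_here) "cis" else "trans")
      origins_a <- c(origins_a,
                     if (dp[1] == 2) "both" else if (pat[1] == 1) "paternal" else "maternal")
      origins_b <- c(origins_b,
                     if (dp[2] == 2) "both" else if (pat[2] == 1) "paternal" else "maternal")
    }
  }
  relation <- if (!support) {
    "mendelian_error"
  } else if (all(relations == "cis")) {
    "cis"
  } else if (all(relations == "trans")) {
    "trans"
  } else {
    "ambiguous"
  }
  origin <- c(NA_character_, NA_character_)
  names(origin) <- c(a, b)
  if (support) {
    if (length(unique(origins_a)) == 1L && origins_a[1] != "both") origin[a] <- origins_a[1]
    if (length(unique(origins_b)) == 1L && origins_b[1] != "both") origin[b] <- origins_b[1]
  }
  phase_call(c(a, b), relation, origin = origin, support = support)
}

phase_call <- function(pair, relation, origin = NULL, support = 0L) {
  structure(list(pair = as.character(pair), relation = relation,
                 origin = origin, support = support),
            class = "phase_call")
}

#' Resolve cis/trans phase of a variant pair from read fragments
#'
#' Counts fragments observing both sites by allele configuration. With
#' `n_aa`, `n_ar`, `n_ra` the (alt,alt), (alt,ref), (ref,alt) counts, the
#' informative alt-involving total is `n_aa + n_ar + n_ra`. The pair is called
#' `cis` when `n_aa >= min_support` and the conflicting fraction
#' `(n_ar + n_ra) / informative` is at most `max_conflict`; symmetrically
#' `trans` when `n_ar + n_ra >= min_support` and `n_aa / informative <=
#' max_conflict`; otherwise `ambiguous` (including when no fragment covers
#' both sites).
#'
#' @param frags A `data.frame` with columns `fragment_id`, `variant_id`,
#'   `allele` (`"ref"` or `"alt"`).
#' @param a,b Variant ids.
#' @param min_support Minimum supporting fragments for a call (default 2, so a
#'   call requires replicated direct observation).
#' @param max_conflict Maximum tolerated conflicting fraction (default 0.1).
#' @return A `phase_call` with `support = c(cis = n_aa, trans = n_ar + n_ra)`.
#' @export
phase_fragments <- function(frags, a, b, min_support = 2L, max_conflict = 0.1) {
  stopifnot(is.data.frame(frags),
            all(c("fragment_id", "variant_id", "allele") %in% names(frags)))
  fa <- frags[frags$variant_id == a, ]
  fb <- frags[frags$variant_id == b, ]
  shared <- intersect(fa$fragment_id, fb$fragment_id)
  aa <- ar <- ra <- 0L
  for (f in shared) {
    oa <- fa$allele[match(f, fa$fragment_id)]
    ob <- fb$allele[match(f, fb$fragment_id)]
    if (oa == "alt" && ob == "alt") aa <- aa + 1L
    else if (oa == "alt" && ob == "ref") ar <- ar + 1L
    else if (oa == "ref" && ob == "alt") ra <- ra + 1L
  }
  informative <- aa + ar + ra
  relation <- "ambiguous"
  if (informative > 0L) {
    if (aa >= min_support && (ar + ra) / informative <= max_conflict) {
      relation <- "cis"
    } else if ((ar + ra) >= min_support && aa / informative <= max_conflict) {
      relation <- "trans"
    }
  }
  phase_call(c(a, b), relation, support = c(cis = aa, trans = ar + ra))
}

#' Combine two phase calls for the same pair
#'
#' Concordant informative calls keep their relation; discordant informative
#' calls (one `cis`, one `trans`, or either a `mendelian_error`) are flagged
#' `conflict`; a single informative call dominates an `ambiguous` one.
#'
#' @param trio_call,frag_call `phase_call` objects (either may be `NULL`).
#' @return A combined `phase_call`.
#' @export
combine_phase_calls <- function(trio_call, frag_call) {
  calls <- Filter(Negate(is.null), list(trio_call, frag_call))
  if (!length(calls)) stop("no phase evidence supplied")
  if (length(calls) == 1L) return(calls[[1]])
  r1 <- calls[[1]]$relation
  r2 <- calls[[2]]$relation
  informative <- function(r) r %in% c("cis", "trans", "mendelian_error")
  relation <- if (informative(r1) && informative(r2)) {
    if (r1 == r2 && r1 != "mendelian_error") r1 else "conflict"
  } else if (informative(r1)) {
    if (r1 == "mendelian_error") "conflict" else r1
  } else if (informative(r2)) {
    if (r2 == "mendelian_error") "conflict" else r2
  } else {
    "ambiguous"
  }
  origin <- calls[[1]]$origin %||% calls[[2]]$origin
  phase_call(calls[[1]]$pair, relation, origin = origin,
             support = calls[[1]]$support)
}

#' Phase all variant pairs carried by one proband
#'
#' Runs trio and/or fragment phasing for every unordered pair of distinct
#' variants the proband carries and combines the evidence with
#' [combine_phase_calls()]. Pairs forced cis by homozygosity are resolved even
#' without external evidence.
#'
#' @param record A [proband_record()].
#' @param trio Optional [trio()] covering the proband's variants.
#' @param fragments Optional fragment `data.frame` (see [phase_fragments()]).
#' @param min_support,max_conflict Passed to [phase_fragments()].
#' @return A list of `phase_call`s, named `"a|b"` per pair.
#' @export
resolve_proband <- function(record, trio = NULL, fragments = NULL,
                            min_support = 2L, max_conflict = 0.1) {
  ids <- sort(carried_variants(record))
  if (length(ids) < 2L) return(list())
  pairs <- combn(ids, 2L, simplify = FALSE)
  calls <- lapply(pairs, function(p) {
    a <- p[1]; b <- p[2]
    tcall <- NULL
    if (!is.null(trio) && all(c(a, b) %in% names(trio$proband)) &&
        !any(is.na(trio$proband[c(a, b)])) && all(trio$proband[c(a, b)] >= 1)) {
      tcall <- phase_trio(trio, a, b)
    }
    fcall <- NULL
    if (!is.null(fragments)) {
      fcall <- phase_fragments(fragments, a, b, min_support, max_conflict)
    }
    call <- if (is.null(tcall) && is.null(fcall)) {
      phase_call(c(a, b), "ambiguous")
    } else {
      combine_phase_calls(tcall, fcall)
    }
    # homozygosity at either site forces one chromosome to carry both
    forced <- record_dosage(record, a) == 2L || record_dosage(record, b) == 2L
    if (call$relation == "ambiguous" && forced) {
      call <- phase_call(c(a, b), "cis", origin = call$origin,
                         support = call$support)
    }
    call
  })
  names(calls) <- vapply(pairs, paste, character(1), collapse = "|")
  calls
}
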