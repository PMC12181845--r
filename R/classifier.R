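#' Default exclusion lexicons for host-string classification
#'
#' Three pattern sets matched (as substrings of the normalized text) against
#' host strings and record source notes: `abiotic` environmental samples
#' (water, soil, mud sediment, ...), `nonliving` substrates (decaying log,
#' fallen branch, ...) and `symbiont` context (endosymbiont, lichen-associated,
#' pathobiome, ...). The sets must be pairwise disjoint after normalization;
#' all are user-extensible.
#'
#' @return A validated list of class `parafind_lexicons` with elements
#'   `abiotic`, `nonliving` and `symbiont`.
#' @export
default_lexicons <- function() {
  lexicons(
    abiotic = c("water", "soil", "mud sediment", "sediment", "sludge",
                "wastewater", "aquifer", "hot spring", "snow", "ice core"),
    nonliving = c("decaying log", "fallen branch", "dead wood", "deadwood",
                  "leaf litter", "detritus", "woody debris"),
    symbiont = c("endosymbiont", "symbiont", "lichen", "pathobiome",
                 "epibiont", "mycobiont", "photobiont")
  )
}

#' Construct and validate exclusion lexicons
#'
#' @param abiotic,nonliving,symbiont Character vectors of substring patterns.
#' @return A list of class `parafind_lexicons`.
#' @export
lexicons <- function(abiotic, nonliving, symbiont) {
  lex <- list(abiotic = norm_text(abiotic), nonliving = norm_text(nonliving),
              symbiont = norm_text(symbiont))
  all_terms <- unlist(lex, use.names = FALSE)
  if (anyDuplicated(all_terms)) {
    stop("lexicon pattern sets must be pairwise disjoint after normalization",
         call. = FALSE)
  }
  structure(lex, class = "parafind_lexicons")
}

#' Classify one host string as live host, abiotic, non-living or symbiont
#'
#' Normalizes (lowercase, trimmed) the string and matches it against the
#' lexicon pattern sets in the order abiotic, non-living, symbiont-context;
#' a string matching none of them denotes a live host. An empty string is
#' treated as abiotic (no live-host evidence).
#'
#' @param host A free-text host string.
#' @param lex Lexicons from [lexicons()] / [default_lexicons()].
#' @return One of `"live_host"`, `"abiotic"`, `"nonliving"`,
#'   `"symbiont_context"`.
#' @export
classify_host_string <- function(host, lex = default_lexicons()) {
  stopifnot(inherits(lex, "parafind_lexicons"))
  h <- norm_text(host)
  if (!length(h) || is.na(h) || !nzchar(h)) return("abiotic")
  match_any <- function(patterns) any(vapply(patterns, grepl, logical(1),
                                             x = h, fixed = TRUE))
  if (match_any(lex$abiotic)) return("abiotic")
  if (match_any(lex$nonliving)) return("nonliving")
  if (match_any(lex$symbiont)) return("symbiont_context")
  "live_host"
}

#' Species-level assignment from the best hit
#'
#' An ASV is assigned to a species when its best hit exceeds the
#' species-level identity threshold (strictly greater than 98% by default)
#' and the hit's reference record is resolved to species rank.
#'
#' @param best_hit One-row hit data.frame (or `NULL`).
#' @param record The matching reference record row (or `NULL`).
#' @param min_identity_species Identity threshold, exceeded strictly.
#' @return The species binomial, or `NA_character_`.
#' @export
assign_species <- function(best_hit, record, min_identity_species = 98) {
  if (is.null(best_hit) || !nrow(best_hit)) return(NA_character_)
  if (is.null(record) || !nrow(record)) return(NA_character_)
  sp <- record$species[1]
  if (is.na(sp) || !nzchar(sp)) return(NA_character_)
  if (best_hit$pident[1] > min_identity_species) sp else NA_character_
}

# symbiont-context flag for a whole record: any host string or the source
# note matching the symbiont lexicon
record_symbiont_context <- function(hosts, source_note, lex) {
  texts <- c(hosts, source_note)
  texts <- texts[!is.na(texts) & nzchar(texts)]
  any(vapply(texts, function(t) {
    classify_host_string(t, lex) == "symbiont_context" ||
      any(vapply(lex$symbiont, grepl, logical(1), x = norm_text(t),
                 fixed = TRUE))
  }, logical(1)))
}

#' Integrate reference-record and literature evidence into a parasite call
#'
#' Implements the evidence-integration rule: an ASV is GenBank-positive when
#' its best hit's reference record carries at least one live-host string and
#' the record is not symbiont-context; it is literature-positive when its
#' species assignment matches a literature row with `is_parasite = TRUE`.
#' Provenance is `both`, `genbank_only`, `literature_only` or `none`; ASVs
#' with provenance `none` are non-parasites with the most informative
#' exclusion reason (symbiont > abiotic > non-living > no host evidence).
#' When literature explicitly marks the species non-parasitic but host
#' metadata is positive, the `conflict_policy` decides (default: host
#' metadata wins; the conflict is flagged in the returned row).
#'
#' @param asv_id ASV identifier.
#' @param best_hit One-row data.frame: the top-bitscore qualifying hit, or
#'   `NULL` when the ASV has none.
#' @param record The reference record of `best_hit`'s subject, or `NULL`.
#' @param literature Literature-evidence data.frame (`species_name`,
#'   `is_parasite`, `hosts`, `source`).
#' @param lex Exclusion lexicons.
#' @param species Species assignment for the ASV (from [assign_species()] or
#'   a dataset-native assignment); `NA` when unassigned.
#' @param conflict_policy `"genbank"` (default) or `"literature"`: which
#'   evidence wins when they disagree.
#' @return One-row data.frame: `asv_id`, `status`, `exclusion_reason`,
#'   `provenance`, `best_hit_accession`, `best_hit_identity`, `species`,
#'   `host_strings`, `conflict`.
#' @export
integrate_evidence <- function(asv_id, best_hit = NULL, record = NULL,
                               literature = NULL, lex = default_lexicons(),
                               species = NA_character_,
                               conflict_policy = c("genbank", "literature")) {
  conflict_policy <- match.arg(conflict_policy)
  hosts <- character(0)
  note <- ""
  if (!is.null(record) && nrow(record)) {
    hosts <- split_multi(record$hosts[1])
    note <- record$source_note[1] %||% ""
    if (is.na(note)) note <- ""
  }

  symbiont <- length(c(hosts[nzchar(hosts)], note[nzchar(note)])) > 0 &&
    record_symbiont_context(hosts, note, lex)
  host_classes <- vapply(hosts, classify_host_string, character(1), lex = lex)
  genbank_positive <- !symbiont && any(host_classes == "live_host")

  lit_row <- NULL
  if (!is.null(literature) && nrow(literature) && !is.na(species)) {
    m <- which(norm_text(literature$species_name) == norm_text(species))
    if (length(m)) lit_row <- literature[m[1], , drop = FALSE]
  }
  literature_positive <- !is.null(lit_row) && isTRUE(lit_row$is_parasite)
  literature_negative <- !is.null(lit_row) && !isTRUE(lit_row$is_parasite)

  conflict <- FALSE
  if (genbank_positive && literature_negative) {
    conflict <- TRUE
    if (conflict_policy == "literature") genbank_positive <- FALSE
  }

  provenance <- if (genbank_positive && literature_positive) "both"
    else if (genbank_positive) "genbank_only"
    else if (literature_positive) "literature_only"
    else "none"

  if (provenance == "none") {
    status <- "non_parasite"
    reason <- if (symbiont) "symbiont"
      else if (any(host_classes == "abiotic")) "abiotic_substrate"
      else if (any(host_classes == "nonliving")) "nonliving_substrate"
      else "no_host_evidence"
  } else {
    status <- "parasite"
    reason <- "none"
  }

  lit_hosts <- if (!is.null(lit_row)) split_multi(lit_row$hosts[1]) else character(0)
  data.frame(
    asv_id = asv_id, status = status, exclusion_reason = reason,
    provenance = provenance,
    best_hit_accession = if (!is.null(best_hit) && nrow(best_hit))
      best_hit$sseqid[1] else NA_character_,
    best_hit_identity = if (!is.null(best_hit) && nrow(best_hit))
      best_hit$pident[1] else NA_real_,
    species = species,
    host_strings = collapse_multi(unique(c(hosts, lit_hosts))),
    conflict = conflict,
    stringsAsFactors = FALSE
  )
}

#' Assign host groups to parasite calls
#'
#' For each parasite call, maps every associated host string (record hosts
#' union literature hosts) through the host-group map and stores the
#' resulting set; a parasite with no resolvable host string gets
#' `"unresolved"`. Non-parasite rows are left untouched (with a warning when
#' called on a purely non-parasite table).
#'
#' @param calls Calls data.frame from [integrate_evidence()] /
#'   [classify_asvs()].
#' @param map Host-group map (see [default_host_group_map()]).
#' @param lex Lexicons used to skip non-live host strings (abiotic strings on
#'   a mixed record are sample context, not hosts).
#' @return `calls` with a `host_groups` column (`|`-collapsed label set).
#' @export
assign_host_groups <- function(calls, map = default_host_group_map(),
                               lex = default_lexicons()) {
  if (!nrow(calls) || all(calls$status != "parasite")) {
    warning("assign_host_groups: no parasite calls; nothing to do", call. = FALSE)
    calls$host_groups <- rep(NA_character_, nrow(calls))
    return(calls)
  }
  calls$host_groups <- NA_character_
  idx <- which(calls$status == "parasite")
  for (i in idx) {
    hosts <- split_multi(calls$host_strings[i])
    hosts <- hosts[vapply(hosts, classify_host_string, character(1),
                          lex = lex) == "live_host"]
    groups <- unique(vapply(hosts, map_host_to_group, character(1), map = map))
    groups <- groups[!is.na(groups)]
    if (!length(groups)) groups <- "unresolved"
    calls$host_groups[i] <- collapse_multi(sort(groups))
  }
  calls
}

#' Classify every ASV as parasite or non-parasite
#'
#' The full classification pipeline for one dataset: thresholds and ranks the
#' hit table ([process_hits()]), selects each ASV's top-bitscore hit, looks up
#' the hit's reference record, derives the species assignment (best-hit route
#' or dataset-native taxonomy), integrates record host metadata with
#' literature evidence ([integrate_evidence()]), and maps host strings to
#' host groups. Every ASV in `asv_ids` receives exactly one call; ASVs
#' without a qualifying hit and without literature evidence are
#' non-parasites with reason `no_host_evidence`.
#'
#' @param hits Hit table (see [parse_hits()]).
#' @param records Reference-record data.frame (`accession`, `lineage`,
#'   `species`, `hosts`, `source_note`, ...).
#' @param literature Literature-evidence data.frame.
#' @param asv_ids Character vector of all ASV ids to call. Defaults to the
#'   query ids present in `hits`.
#' @param taxonomy Optional dataset-native taxonomy (`asv_id`, `species`):
#'   supplies species assignments for ASVs whose best hit does not resolve
#'   one.
#' @param lex,map Lexicons and host-group map.
#' @param min_identity,min_cover,max_hits Hit retention thresholds
#'   (defaults 90, 100, 10).
#' @param species_identity Species-assignment identity threshold (strict >).
#' @param conflict_policy See [integrate_evidence()].
#' @return data.frame of class `parasite_calls`, one row per ASV.
#' @export
classify_asvs <- function(hits, records, literature = NULL, asv_ids = NULL,
                          taxonomy = NULL, lex = default_lexicons(),
                          map = default_host_group_map(),
                          min_identity = 90, min_cover = 100, max_hits = 10,
                          species_identity = 98,
                          conflict_policy = c("genbank", "literature")) {
  conflict_policy <- match.arg(conflict_policy)
  asv_ids <- asv_ids %||% unique(hits$qseqid)
  ranked <- process_hits(hits, min_identity, min_cover, max_hits)
  best <- best_hits(ranked)

  rows <- vector("list", length(asv_ids))
  for (k in seq_along(asv_ids)) {
    id <- asv_ids[k]
    bh <- best[best$qseqid == id, , drop = FALSE]
    if (!nrow(bh)) bh <- NULL
    rec <- NULL
    if (!is.null(bh)) {
      rec <- records[records$accession == bh$sseqid[1], , drop = FALSE]
      if (!nrow(rec)) rec <- NULL
    }
    sp <- assign_species(bh, rec, species_identity)
    if (is.na(sp) && !is.null(taxonomy)) {
      tx <- taxonomy[taxonomy$asv_id == id, , drop = FALSE]
      if (nrow(tx) && !is.na(tx$species[1]) && nzchar(tx$species[1])) {
        sp <- tx$species[1]
      }
    }
    rows[[k]] <- integrate_evidence(id, bh, rec, literature, lex, sp,
                                    conflict_policy)
  }
  calls <- do.call(rbind, rows)
  if (any(calls$status == "parasite")) {
    calls <- assign_host_groups(calls, map, lex)
  } else {
    calls$host_groups <- NA_character_
  }
  class(calls) <- c("parasite_calls", class(calls))
  calls
}

#' Provenance accounting for a set of parasite calls
#'
#' @param calls A `parasite_calls` data.frame.
#' @return List: `total`, `parasites`, `non_parasites`, `by_provenance`
#'   (named both / literature_only / genbank_only), `pct_parasites`, and
#'   `consistent` (the partition identities hold).
#' @export
call_accounting <- function(calls) {
  par <- calls$status == "parasite"
  by_prov <- c(
    both = sum(calls$provenance == "both"),
    literature_only = sum(calls$provenance == "literature_only"),
    genbank_only = sum(calls$provenance == "genbank_only")
  )
  out <- list(
    total = nrow(calls),
    parasites = sum(par),
    non_parasites = sum(!par),
    by_provenance = by_prov,
    pct_parasites = 100 * sum(par) / max(nrow(calls), 1)
  )
  out$consistent <- (out$parasites + out$non_parasites == out$total) &&
    (sum(by_prov) == out$parasites)
  out
}

#' Accounting identities from provenance-category component counts
#'
#' Combines per-provenance parasite counts into the summary quantities a
#' survey reports: total parasites, their percentage of the dataset, and the
#' consistency of the decomposition. Useful for checking published component
#' counts against their printed totals.
#'
#' @param both,literature_only,genbank_only Parasite ASV counts per
#'   evidence-provenance category.
#' @param total_asvs Total ASVs in the dataset (after decontamination).
#' @return List: `parasites`, `pct_parasites`, `non_parasites`.
#' @export
provenance_accounting <- function(both, literature_only, genbank_only,
                                  total_asvs) {
  stopifnot(is_count(both), is_count(literature_only), is_count(genbank_only),
            is_count(total_asvs))
  parasites <- both + literature_only + genbank_only
  list(parasites = parasites,
       pct_parasites = 100 * parasites / total_asvs,
       non_parasites = total_asvs - parasites)
}

#' @export
print.parasite_calls <- function(x, ...) {
  acc <- call_accounting(x)
  cat(sprintf("Parasite calls for %d ASVs: %d parasites (%.1f%%), %d non-parasites\n",
              acc$total, acc$parasites, acc$pct_parasites, acc$non_parasites))
  cat(sprintf("  provenance: both %d | literature only %d | genbank only %d\n",
              acc$by_provenance["both"], acc$by_provenance["literature_only"],
              acc$by_provenance["genbank_only"]))
  invisible(x)
}
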