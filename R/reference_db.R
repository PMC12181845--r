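#' Assemble a taxon-scoped reference collection
#'
#' Retains reference records whose taxonomic lineage intersects a set of scope
#' taxa (case-insensitive match against any lineage element), plus any
#' explicitly whitelisted accessions. Input order is preserved. Typical scopes
#' are parasite-containing higher taxa, e.g. `"Chytridiomycota"` or the
#' helminth groups `Cestoda`, `Nematoda`, `Monogenea`, `Digenea`, `Trematoda`
#' and `Acanthocephala`.
#'
#' @param records Reference-record data.frame with columns `accession` and
#'   `lineage` (semicolon-separated, root to species).
#' @param taxon_scope Character vector of taxa defining the collection scope.
#' @param whitelist Accessions retained regardless of lineage.
#' @return The scope-filtered records, original order preserved. An empty
#'   result triggers a warning, not an error.
#' @export
build_collection <- function(records, taxon_scope, whitelist = character(0)) {
  stopifnot(is.data.frame(records),
            all(c("accession", "lineage") %in% names(records)))
  if (length(taxon_scope) == 0) stop("`taxon_scope` must be non-empty", call. = FALSE)
  if (anyDuplicated(records$accession)) {
    stop("duplicate accessions in `records`", call. = FALSE)
  }
  scope <- norm_text(taxon_scope)
  keep <- vapply(records$lineage, function(l) {
    any(norm_text(strsplit(l, ";", fixed = TRUE)[[1]]) %in% scope)
  }, logical(1), USE.NAMES = FALSE)
  keep <- keep | records$accession %in% whitelist
  out <- records[keep, , drop = FALSE]
  if (!nrow(out)) {
    warning("taxon scope matched no records; collection is empty", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Remove duplicate sequences from a reference collection
#'
#' Collapses records sharing an identical full-length sequence (compared after
#' uppercasing) to a single record, keeping the first-seen accession.
#' Near-duplicates (any base difference) are kept. Records without a sequence
#' are passed through unchanged with a warning.
#'
#' @param records Reference-record data.frame with a `sequence` column.
#' @return Deduplicated records; the number of removed duplicates is reported
#'   via `message()` and attached as attribute `n_removed`.
#' @export
dedup_sequences <- function(records) {
  stopifnot(is.data.frame(records))
  if (is.null(records$sequence)) {
    stop("`records` lacks a `sequence` column", call. = FALSE)
  }
  seqs <- toupper(records$sequence)
  missing <- is.na(seqs) | !nzchar(seqs)
  if (any(missing)) {
    warning(sprintf("%d record(s) lack sequences and were passed through",
                    sum(missing)), call. = FALSE)
  }
  dup <- duplicated(seqs) & !missing
  out <- records[!dup, , drop = FALSE]
  rownames(out) <- NULL
  n_removed <- sum(dup)
  message(sprintf("dedup_sequences: removed %d duplicate sequence(s)", n_removed))
  attr(out, "n_removed") <- n_removed
  out
}

#' Default host-string to host-group mapping
#'
#' An ordered rule table translating free-text host strings (mixed-rank
#' binomials, genus names, lineage fragments) to broad host groups. Matching
#' tries exact species name first, then genus, then lineage/substring rules;
#' the first matching rule wins and unmatched strings map to `"unresolved"`.
#' The table is plain data and can be extended or reordered by the user.
#'
#' @return data.frame with columns `pattern`, `match` (`exact`, `genus` or
#'   `contains`) and `group`.
#' @export
default_host_group_map <- function() {
  rule <- function(pattern, match, group) {
    data.frame(pattern = pattern, match = match, group = group,
               stringsAsFactors = FALSE)
  }
  rbind(
    rule("homo sapiens", "exact", "humans"),
    rule(c("asterionella", "ulnaria", "synedra", "fragilaria"), "genus", "diatoms"),
    rule(c("desmodesmus", "scenedesmus", "haematococcus", "staurastrum",
           "chlorogonium", "chlorella", "chara", "cladophora"), "genus",
         "green_algae"),
    rule(c("peridinium", "ceratium"), "genus", "dinoflagellates"),
    rule(c("daphnia", "cyclops", "astacus", "bosmina"), "genus", "crustaceans"),
    rule(c("rhizophydium", "zygorhizidium"), "genus", "fungi"),
    rule(c("zea", "quercus", "triticum", "poa"), "genus", "terrestrial_plants"),
    rule(c("salamandra", "triturus", "ambystoma"), "genus", "salamanders"),
    rule("vallisneria", "genus", "aquatic_plants"),
    rule(c("paramecium", "vorticella"), "genus", "other_protists"),
    rule(c("elliptio", "dreissena"), "genus", "other_metazoans"),
    # lineage-fragment fallbacks for strings carrying rank names
    rule(c("chlorophyceae", "chlorophyta"), "contains", "green_algae"),
    rule(c("bacillariophy"), "contains", "diatoms"),
    rule(c("dinophyceae", "dinoflagellata"), "contains", "dinoflagellates")
  )
}

#' Map one host string to a host group
#'
#' Applies the ordered rules of a host-group map (see
#' [default_host_group_map()]): first an exact-name pass, then genus (first
#' word) rules, then substring rules; first match wins. Matching is
#' case-insensitive and ignores surrounding whitespace.
#'
#' @param host A free-text host string.
#' @param map Host-group map data.frame.
#' @return A group label, or `"unresolved"` when no rule matches.
#' @export
map_host_to_group <- function(host, map = default_host_group_map()) {
  stopifnot(is.data.frame(map),
            all(c("pattern", "match", "group") %in% names(map)))
  h <- norm_text(host)
  if (!length(h) || is.na(h) || !nzchar(h)) return("unresolved")
  genus <- strsplit(h, " ", fixed = TRUE)[[1]][1]
  for (tier in c("exact", "genus", "contains")) {
    rules <- map[map$match == tier, , drop = FALSE]
    for (k in seq_len(nrow(rules))) {
      pat <- norm_text(rules$pattern[k])
      hit <- switch(tier,
                    exact = identical(h, pat),
                    genus = identical(genus, pat),
                    contains = grepl(pat, h, fixed = TRUE))
      if (hit) return(rules$group[k])
    }
  }
  "unresolved"
}
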