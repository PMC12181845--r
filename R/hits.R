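#' @keywords internal
empty_hit_table <- function() {
  data.frame(qseqid = character(0), sseqid = character(0),
             pident = numeric(0), length = integer(0), mismatch = integer(0),
             gapopen = integer(0), qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0), evalue = numeric(0),
             bitscore = numeric(0), qcovs = numeric(0),
             stringsAsFactors = FALSE)
}

.hit_required <- c("qseqid", "sseqid", "pident", "evalue", "bitscore", "qcovs")
.hit_positional <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                     "gapopen", "qstart", "qend", "sstart", "send",
                     "evalue", "bitscore", "qcovs")

#' Parse a tabular similarity-hit file
#'
#' Reads a tab-separated hit table in `outfmt 6` column order with an
#' appended query-cover (`qcovs`) column, with or without a header line.
#' Numeric fields are parsed locale-independently; malformed rows raise a
#' format error citing their row numbers. Extra columns are ignored.
#'
#' @param path Path to the TSV file.
#' @param sep Field delimiter (tab by default).
#' @return data.frame of hits with at least columns `qseqid`, `sseqid`,
#'   `pident`, `evalue`, `bitscore`, `qcovs`. An empty file yields an empty
#'   table with a warning.
#' @export
parse_hits <- function(path, sep = "\t") {
  if (!file.exists(path)) stop(sprintf("hit file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first)) {
    warning("empty hit file: returning no hits", call. = FALSE)
    return(empty_hit_table())
  }
  has_header <- grepl("qseqid|query", strsplit(first, sep, fixed = TRUE)[[1]][1],
                      ignore.case = TRUE)
  df <- utils::read.table(path, sep = sep, header = has_header,
                          colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(df) < length(.hit_positional)) {
      stop(sprintf("hit file has %d columns; expected >= %d (outfmt 6 + qcovs)",
                   ncol(df), length(.hit_positional)), call. = FALSE)
    }
    names(df)[seq_along(.hit_positional)] <- .hit_positional
  }
  missing <- setdiff(.hit_required, names(df))
  if (length(missing)) {
    stop(sprintf("hit file lacks required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  numcols <- intersect(c("pident", "length", "mismatch", "gapopen", "qstart",
                         "qend", "sstart", "send", "evalue", "bitscore",
                         "qcovs"), names(df))
  bad <- integer(0)
  for (cc in numcols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- union(bad, which(is.na(v) & !is.na(df[[cc]])))
    df[[cc]] <- v
  }
  if (length(bad)) {
    stop(sprintf("malformed numeric value(s) in hit file row(s): %s",
                 paste(sort(bad), collapse = ", ")), call. = FALSE)
  }
  df
}

#' Filter hits on identity and query-cover thresholds
#'
#' Retains hits with `pident >= min_identity` and query cover (rounded to one
#' decimal, tolerating reporting dialects that print 99.97 as 100)
#' `>= min_cover`. Both comparisons are inclusive.
#'
#' @param hits Hit data.frame (see [parse_hits()]).
#' @param min_identity Minimum percent identity (default 90).
#' @param min_cover Minimum percent query cover (default 100).
#' @return The retained hits.
#' @export
filter_hits <- function(hits, min_identity = 90, min_cover = 100) {
  stopifnot(min_identity >= 0, min_identity <= 100,
            min_cover >= 0, min_cover <= 100)
  if (!nrow(hits)) return(hits)
  keep <- hits$pident >= min_identity & round(hits$qcovs, 1) >= min_cover
  out <- hits[keep & !is.na(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# total deterministic ordering of hits: bitscore desc, evalue asc,
# pident desc, accession asc
hit_order <- function(hits) {
  order(-hits$bitscore, hits$evalue, -hits$pident, hits$sseqid,
        method = "radix")
}

#' Rank hits per query and keep the top scorers
#'
#' Orders each query's hits by descending bitscore, breaking ties by
#' ascending e-value, then descending identity, then accession, and keeps at
#' most `max_hits` per query. The first retained hit is the best hit whose
#' reference metadata feeds classification. The full tie-break key makes the
#' selection a pure function of the hit set: row order never matters.
#'
#' @param hits Hit data.frame, typically already threshold-filtered.
#' @param max_hits Maximum retained hits per query (default 10).
#' @return Hits with a `rank` column (1 = best), ordered by query then rank.
#' @export
rank_hits <- function(hits, max_hits = 10) {
  stopifnot(max_hits >= 1)
  if (!nrow(hits)) {
    out <- hits
    out$rank <- integer(0)
    return(out)
  }
  ord <- hit_order(hits)
  out <- hits[ord, , drop = FALSE]
  out <- out[order(match(out$qseqid, unique(hits$qseqid)), method = "radix"),
             , drop = FALSE]  # radix sort is stable: within-query order kept
  ranks <- stats::ave(seq_len(nrow(out)), out$qseqid, FUN = seq_along)
  out$rank <- as.integer(ranks)
  out <- out[out$rank <= max_hits, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter, rank and truncate hits in one step
#'
#' Applies [filter_hits()] then [rank_hits()] (the default), or ranks and
#' truncates before filtering when `filter_first = FALSE` (the alternative
#' reading of "top ten qualifying hits").
#'
#' @inheritParams filter_hits
#' @inheritParams rank_hits
#' @param filter_first Apply thresholds before taking the top `max_hits`.
#' @return Ranked, retained hits (see [rank_hits()]).
#' @export
process_hits <- function(hits, min_identity = 90, min_cover = 100,
                         max_hits = 10, filter_first = TRUE) {
  if (filter_first) {
    rank_hits(filter_hits(hits, min_identity, min_cover), max_hits)
  } else {
    out <- filter_hits(rank_hits(hits, max_hits), min_identity, min_cover)
    # re-rank after filtering so ranks stay contiguous
    out$rank <- NULL
    rank_hits(out, max_hits)
  }
}

#' Best hit per query
#'
#' @param hits Ranked hits from [rank_hits()] or [process_hits()] (a `rank`
#'   column is added if absent).
#' @return One row per query: the top-bitscore hit under the deterministic
#'   tie-break key.
#' @export
best_hits <- function(hits) {
  if (is.null(hits$rank)) hits <- rank_hits(hits)
  out <- hits[hits$rank == 1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}
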