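#' Write a synthetic study to plain-text files
#'
#' Serializes the study to TSV files (counts, sample metadata, ground truth,
#' taxonomy, reference records, literature, hits) and the ASV sequences to
#' FASTA, plus a `schema.tsv` documenting every column. Multi-value fields
#' are `|`-collapsed.
#'
#' @param study A `parafind_study`, typically from [demo_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_tsv <- function(df, f) {
    utils::write.table(df, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  counts_df <- data.frame(sample_id = rownames(study$counts), study$counts,
                          check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(counts_df, "counts.tsv")
  write_tsv(study$metadata, "metadata.tsv")
  write_tsv(study$truth, "truth.tsv")
  write_tsv(study$taxonomy, "taxonomy.tsv")
  if (!is.null(study$records)) write_tsv(study$records, "references.tsv")
  if (!is.null(study$literature)) write_tsv(study$literature, "literature.tsv")
  if (!is.null(study$hits)) write_tsv(study$hits, "hits.tsv")
  write_fasta(study$sequences, p("asvs.fasta"))
  schema <- data.frame(
    file = c("counts.tsv", "metadata.tsv", "truth.tsv", "taxonomy.tsv",
             "references.tsv", "literature.tsv", "hits.tsv", "asvs.fasta"),
    columns = c(
      "sample_id + one integer column per ASV",
      "sample_id, lake, lake_type, season, year, run, is_negative_control",
      "asv_id, group, dataset, lineage, is_parasite, host_group, habitat_preference, is_contaminant, provenance_planned, nonparasite_route",
      "asv_id, dataset, lineage, species",
      "accession, lineage, species, marker, hosts (|-sep), source_note, sequence",
      "species_name, is_parasite, hosts (|-sep), source",
      "outfmt 6 columns qseqid..bitscore plus qcovs",
      "one record per ASV, id = asv_id"),
    stringsAsFactors = FALSE)
  write_tsv(schema, "schema.tsv")
  files <- c("counts.tsv", "metadata.tsv", "truth.tsv", "taxonomy.tsv",
             "references.tsv", "literature.tsv", "hits.tsv", "asvs.fasta",
             "schema.tsv")
  invisible(stats::setNames(file.path(dir, files), files))
}

#' Write named sequences to FASTA
#'
#' Uses Biostrings when available, otherwise plain writeLines.
#'
#' @param sequences Named character vector of nucleotide sequences.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  } else {
    writeLines(paste0(">", names(sequences), "\n", sequences), path)
  }
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    stats::setNames(as.character(x), names(x))
  } else {
    lines <- readLines(path)
    idx <- grepl("^>", lines)
    ids <- sub("^>", "", lines[idx])
    grp <- cumsum(idx)
    seqs <- vapply(split(lines[!idx], grp[!idx]), paste, character(1),
                   collapse = "")
    stats::setNames(unname(seqs), ids)
  }
}

#' Read a counts TSV (samples x ASVs) back into a matrix
#'
#' @param path Path to a `counts.tsv` written by [write_study()].
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Serialize a pipeline run report to JSON
#'
#' @param result A `parafind_result`.
#' @param path Output path for the JSON report.
#' @export
write_report <- function(result, path) {
  r <- result$report
  out <- list(
    n_samples = r$n_samples,
    n_negative_controls = r$n_negative_controls,
    n_asvs_input = r$n_asvs_input,
    n_asvs_retained = r$n_asvs_retained,
    decontam = r$decontam,
    accounting = list(
      total = r$accounting$total,
      parasites = r$accounting$parasites,
      non_parasites = r$accounting$non_parasites,
      by_provenance = as.list(r$accounting$by_provenance),
      pct_parasites = r$accounting$pct_parasites,
      consistent = r$accounting$consistent),
    focal_group_sizes = as.list(r$focal_group_sizes),
    n_indicators = r$n_indicators,
    thresholds = r$thresholds,
    seed = r$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
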