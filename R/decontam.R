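#' Remove contaminant ASVs detected in negative controls
#'
#' A contaminant is any ASV with a non-zero count in a no-template negative
#' control. By default removal is per sequencing run: an ASV contaminating
#' run 1's control is zeroed only in run 1's samples (set
#' `per_run = FALSE` to remove contaminants across all runs). Negative
#' controls are dropped from the output, as are ASV columns left with zero
#' total reads. A run without a negative control triggers a warning and no
#' removal for that run.
#'
#' @param counts Integer matrix, samples x ASVs, rownames = sample ids.
#' @param metadata Sample metadata with columns `sample_id`, `run`,
#'   `is_negative_control` covering every row of `counts`.
#' @param per_run Remove per run (default) or globally.
#' @return List: `counts` (decontaminated, controls dropped) and `report`, a
#'   data.frame per run with `run`, `n_contaminants`, `contaminant_asvs`
#'   (`|`-collapsed) and `removed_read_fraction` (removed reads over the
#'   run's lake-sample reads).
#' @export
remove_contaminants <- function(counts, metadata, per_run = TRUE) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  need <- c("sample_id", "run", "is_negative_control")
  stopifnot(all(need %in% names(metadata)))
  missing <- setdiff(rownames(counts), metadata$sample_id)
  if (length(missing)) {
    stop(sprintf("samples missing from metadata: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  md <- metadata[match(rownames(counts), metadata$sample_id), ]
  runs <- unique(md$run)
  out <- counts
  reports <- vector("list", length(runs))
  for (r in seq_along(runs)) {
    run <- runs[r]
    in_run <- md$run == run
    ctrl <- in_run & md$is_negative_control
    smp <- in_run & !md$is_negative_control
    if (!any(ctrl)) {
      warning(sprintf("run %s has no negative control; nothing removed", run),
              call. = FALSE)
      reports[[r]] <- data.frame(run = run, n_contaminants = 0L,
                                 contaminant_asvs = "",
                                 removed_read_fraction = 0,
                                 stringsAsFactors = FALSE)
      next
    }
    contam <- colnames(counts)[colSums(counts[ctrl, , drop = FALSE] > 0) > 0]
    target <- if (per_run) smp else !md$is_negative_control
    total <- sum(counts[smp, , drop = FALSE])
    removed <- sum(counts[smp, contam, drop = FALSE])
    out[target, contam] <- 0L
    reports[[r]] <- data.frame(
      run = run, n_contaminants = length(contam),
      contaminant_asvs = collapse_multi(contam),
      removed_read_fraction = if (total > 0) removed / total else 0,
      stringsAsFactors = FALSE)
  }
  out <- out[!md$is_negative_control, , drop = FALSE]
  out <- out[, colSums(out) > 0, drop = FALSE]
  list(counts = out, report = do.call(rbind, reports))
}
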