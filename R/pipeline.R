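#' Run the full analysis pipeline on a study
#'
#' Orchestrates the stages end to end: negative-control decontamination,
#' hit thresholding and ranking, parasite classification, focal-group
#' selection and richness tables, Poisson richness models with Type-III
#' Wald tests, host-richness correlation post-hoc GLMs, and the indicator
#' permutation analysis. Returns a run report whose accounting always
#' satisfies `total = parasites + non_parasites` and
#' `parasites = both + literature_only + genbank_only`.
#'
#' @param study A `parafind_study` carrying `counts`, `metadata`, `hits`,
#'   `records`, `literature` and `taxonomy` (see [demo_study()], or build
#'   the list from files read with [read_counts()] and [parse_hits()]).
#' @param min_identity,min_cover,max_hits,species_identity Classification
#'   thresholds (defaults 90, 100, 10, 98).
#' @param alpha Indicator significance level (default 0.05).
#' @param n_perm Label permutations for the indicator test (default 9999).
#' @param random_terms Random intercepts requested for the richness models
#'   (singular fits fall back to fixed effects).
#' @param seed Seed for the permutation stream.
#' @return List of class `parafind_result`: `calls`, `decontam`,
#'   `assignment`, `richness`, `models` (named `richness_fit`s),
#'   `host_posthoc`, `indicators`, and `report` (per-stage accounting).
#' @export
run_pipeline <- function(study, min_identity = 90, min_cover = 100,
                         max_hits = 10, species_identity = 98,
                         alpha = 0.05, n_perm = 9999,
                         random_terms = c("lake", "run", "year"),
                         seed = 1L) {
  need <- c("counts", "metadata", "hits", "records")
  miss <- need[!need %in% names(study)]
  if (length(miss)) {
    stop(sprintf("study lacks component(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }

  dec <- remove_contaminants(study$counts, study$metadata)
  counts <- dec$counts
  asv_ids <- colnames(counts)

  calls <- classify_asvs(study$hits, study$records, study$literature,
                         asv_ids = asv_ids, taxonomy = study$taxonomy,
                         min_identity = min_identity, min_cover = min_cover,
                         max_hits = max_hits,
                         species_identity = species_identity)
  acc <- call_accounting(calls)

  # ASV taxonomy: best-hit record lineage, falling back to the
  # dataset-native assignment
  best <- best_hits(process_hits(study$hits, min_identity, min_cover, max_hits))
  lin <- study$records$lineage[match(best$sseqid, study$records$accession)]
  taxa <- data.frame(asv_id = best$qseqid, lineage = lin,
                     dataset = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(study$taxonomy)) {
    native <- study$taxonomy
    taxa$dataset <- native$dataset[match(taxa$asv_id, native$asv_id)]
    extra <- native[!native$asv_id %in% taxa$asv_id,
                    c("asv_id", "lineage", "dataset")]
    taxa <- rbind(taxa, extra)
  }

  assignment <- select_focal_groups(calls, taxa)

  host_asvs <- character(0)
  if (!is.null(study$taxonomy)) {
    host_pat <- "Chlorophyta|Charophyta|Chromista|Gyrista|Dinoflagellata"
    tx <- study$taxonomy
    host_asvs <- tx$asv_id[tx$dataset == "protist" &
                             grepl(host_pat, tx$lineage) &
                             !tx$asv_id %in% calls$asv_id[calls$status == "parasite"]]
  }
  richness <- compute_richness(counts, assignment, study$metadata,
                               host_asvs = if (length(host_asvs)) host_asvs else NULL)

  models <- list()
  for (g in unique(assignment$group)) {
    include_host <- g == "chytrids" && "host_richness" %in% names(richness)
    rt <- richness
    if (include_host) {
      # drop salamander-host chytrids from the host-correlation model input
      drop_ids <- assignment$asv_id[assignment$exclude_from_host_corr]
      if (length(drop_ids)) {
        keep <- assignment[assignment$group == "chytrids" &
                             !assignment$asv_id %in% drop_ids, ]
        rt_counts <- counts[, intersect(keep$asv_id, colnames(counts)),
                            drop = FALSE]
        rt$chytrids <- as.integer(rowSums(rt_counts >= 1))
      }
    }
    models[[g]] <- fit_richness_model(rt, g, include_host = include_host,
                                      random_terms = random_terms)
  }

  host_posthoc <- NULL
  if ("chytrids" %in% names(models) && "host_richness" %in% names(richness)) {
    host_posthoc <- host_correlation_posthoc(richness, "chytrids")
  }

  par_ids <- calls$asv_id[calls$status == "parasite"]
  ind_counts <- counts[, intersect(par_ids, colnames(counts)), drop = FALSE]
  groups <- study$metadata$lake_type[match(rownames(ind_counts),
                                           study$metadata$sample_id)]
  indicators <- indicator_analysis(ind_counts, groups, n_perm = n_perm,
                                   seed = seed)
  sig <- call_indicators(indicators, alpha = alpha)

  report <- list(
    n_samples = sum(!study$metadata$is_negative_control),
    n_negative_controls = sum(study$metadata$is_negative_control),
    n_asvs_input = ncol(study$counts),
    decontam = dec$report,
    n_asvs_retained = ncol(counts),
    accounting = acc,
    focal_group_sizes = table(assignment$group),
    n_indicators = nrow(sig),
    indicators_by_habitat = table(sig$preferred_group),
    thresholds = list(min_identity = min_identity, min_cover = min_cover,
                      max_hits = max_hits, species_identity = species_identity,
                      alpha = alpha, n_perm = n_perm),
    seed = seed
  )

  structure(list(calls = calls, decontam = dec, assignment = assignment,
                 richness = richness, models = models,
                 host_posthoc = host_posthoc, indicators = indicators,
                 significant_indicators = sig, report = report),
            class = "parafind_result")
}

#' One-command synthetic demonstration
#'
#' Generates a synthetic study ([demo_study()]) and runs the full pipeline
#' on it. With the default configuration this takes well under a minute.
#'
#' @param seed Integer seed for study generation and permutations.
#' @param config Optional [sim_config()] overriding the defaults.
#' @param n_perm Indicator permutations (999 by default here, for speed).
#' @param random_terms Random intercepts for the richness models; defaults
#'   to none so the demo exercises the fixed-effects path end to end.
#' @return A `parafind_result` with the generating `study` attached.
#' @export
demo_pipeline <- function(seed = 1L, config = NULL, n_perm = 999,
                          random_terms = character(0)) {
  study <- demo_study(seed = seed, config = config)
  res <- run_pipeline(study, n_perm = n_perm, seed = seed,
                      random_terms = random_terms)
  res$study <- study
  res
}

#' Multiplier-recovery and calibration experiment for the richness model
#'
#' Repeatedly generates synthetic studies that inject only a heated-lake
#' richness multiplier (no planted indicator ASVs, no between-lake
#' heterogeneity), fits the fixed-effects Poisson richness model to the
#' aphelid group (the focal group without host-richness coupling), and
#' records whether the 95% Wald interval of the heated/control log-ratio
#' contrast covers `log(multiplier)` and whether the Type-III lake-type test
#' rejects at `alpha`. With `multiplier = 1` the rejection rate estimates the
#' test's type-I error.
#'
#' @param multiplier Injected heated-lake richness multiplier.
#' @param n_sims Number of simulated studies.
#' @param seed Base seed; simulation `i` uses `seed + i`.
#' @param alpha Test level.
#' @return data.frame per simulation: `estimate`, `lower`, `upper`,
#'   `covered`, `p_lake_type`, `reject`.
#' @export
multiplier_recovery <- function(multiplier = 2, n_sims = 100, seed = 1L,
                                alpha = 0.05) {
  out <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    cfg <- sim_config(heated_richness_multiplier = multiplier, lake_sd = 0,
                      n_heated_indicators = 0L, n_control_indicators = 0L,
                      seed = seed + i)
    study <- generate_study(cfg)
    md <- study$metadata[!study$metadata$is_negative_control, ]
    tr <- study$truth
    asn <- data.frame(asv_id = tr$asv_id[tr$group == "aphelids"],
                      group = "aphelids", stringsAsFactors = FALSE)
    tab <- compute_richness(study$counts[md$sample_id, , drop = FALSE], asn,
                            study$metadata)
    fit <- fit_richness_model(tab, "aphelids")
    ct <- lake_type_contrast(fit)
    p_lt <- fit$anova$p_value[fit$anova$term == "lake_type"]
    out[[i]] <- data.frame(
      estimate = ct$estimate, lower = ct$lower, upper = ct$upper,
      covered = ct$lower <= log(multiplier) & log(multiplier) <= ct$upper,
      p_lake_type = p_lt, reject = p_lt < alpha)
  }
  do.call(rbind, out)
}

#' Agreement between parasite calls and planted ground truth
#'
#' @param calls `parasite_calls` from the pipeline.
#' @param truth Ground-truth table from [generate_study()].
#' @return List: `agreement` (fraction of classified ASVs whose
#'   parasite/non-parasite status matches the plan), `provenance_agreement`
#'   (fraction with the planned provenance category), `n`.
#' @export
truth_agreement <- function(calls, truth) {
  tr <- truth[match(calls$asv_id, truth$asv_id), ]
  status_ok <- (calls$status == "parasite") == tr$is_parasite
  prov_ok <- calls$provenance == tr$provenance_planned
  list(agreement = mean(status_ok), provenance_agreement = mean(prov_ok),
       n = nrow(calls))
}

#' @export
print.parafind_result <- function(x, ...) {
  r <- x$report
  cat("parafind pipeline result\n")
  cat(sprintf("  samples: %d (+%d negative controls), ASVs: %d -> %d after decontamination\n",
              r$n_samples, r$n_negative_controls, r$n_asvs_input,
              r$n_asvs_retained))
  a <- r$accounting
  cat(sprintf("  parasites: %d of %d ASVs (%.1f%%) = both %d + literature %d + genbank %d\n",
              a$parasites, a$total, a$pct_parasites,
              a$by_provenance["both"], a$by_provenance["literature_only"],
              a$by_provenance["genbank_only"]))
  if (length(r$focal_group_sizes)) {
    cat("  focal groups:",
        paste(sprintf("%s=%d", names(r$focal_group_sizes),
                      as.integer(r$focal_group_sizes)), collapse = ", "), "\n")
  }
  cat(sprintf("  indicator ASVs (Sidak p < %.2f): %d\n",
              r$thresholds$alpha, r$n_indicators))
  invisible(x)
}
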