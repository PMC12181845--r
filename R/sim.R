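#' Configuration for a synthetic heated/control lake survey
#'
#' Builds and validates the configuration driving [generate_study()] and
#' [generate_reference_and_hits()]. Defaults emulate a two-year seasonal eDNA
#' survey of five artificially heated and five control lakes, with parasite
#' ASVs of known host group, planted habitat-preference (indicator) ASVs,
#' negative-control contaminants, and a positive host--parasite richness
#' coupling for chytrids.
#'
#' Occupancy of an ASV in a lake sample is Bernoulli with probability
#' `occupancy_baseline` scaled multiplicatively (on the log scale) by a season
#' effect, a lake-level lognormal offset, the `heated_richness_multiplier` for
#' groups listed in `heated_groups` when the lake is heated, and a shared
#' per-sample latent factor coupling chytrid occupancy to host-group occupancy
#' with elasticity `host_parasite_slope`. ASVs with a planted habitat
#' preference instead occupy preferred-habitat samples with probability
#' `indicator_occupancy[1]` and the other habitat with
#' `indicator_occupancy[2]`. Probabilities are capped at 0.95.
#'
#' @param n_heated_lakes,n_control_lakes Number of lakes per habitat type.
#' @param seasons Ordered season labels.
#' @param years Calendar years surveyed; each year maps to one sequencing run.
#' @param n_asvs_per_group Named integer vector of ASV counts per simulated
#'   group. Recognised parasite groups: `chytrids`, `aphelids`,
#'   `peronosporomycetes`, `cryptomycota`, `other_parasites`,
#'   `terrestrial_parasites`; non-parasite groups: `green_algae`, `diatoms`,
#'   `dinoflagellates`, `bystander`. `NULL` uses the documented defaults.
#' @param parasite_fraction Optional target fraction of parasite ASVs; when
#'   given (and `n_asvs_per_group` is `NULL`) the `bystander` group is resized
#'   so parasites make up this fraction.
#' @param heated_richness_multiplier Multiplicative effect of heated lakes on
#'   the occupancy (hence expected richness) of `heated_groups`.
#' @param heated_groups Groups receiving the heated-lake multiplier.
#' @param season_effects Named numeric, log-scale occupancy offsets per season.
#' @param host_parasite_slope Elasticity coupling chytrid occupancy to the
#'   per-sample latent factor shared with host groups (0 = no coupling).
#' @param latent_sd,lake_sd Standard deviations of the per-sample latent factor
#'   and of the per-lake lognormal occupancy offset.
#' @param contaminant_count Number of contaminant ASVs planted in negative
#'   controls (alternating between sequencing runs).
#' @param occupancy_baseline Baseline per-sample occupancy probability.
#' @param n_heated_indicators,n_control_indicators Number of parasite ASVs
#'   given a planted habitat preference.
#' @param indicator_occupancy Length-2 numeric: occupancy probability in the
#'   preferred and the non-preferred habitat.
#' @param summer_masked_year2 Drop summer sampling in the second year
#'   (the survey design this generator emulates lacks those samples).
#' @param autumn_extra_year1 Add a second autumn sampling event in the first
#'   year (off by default; the default design has one event per
#'   lake x season x year cell).
#' @param mean_read_count Mean read count of an ASV when present.
#' @param seed Integer seed; identical configurations yield identical studies.
#' @return A validated list of class `sim_config`.
#' @seealso [generate_study()], [generate_reference_and_hits()], [demo_study()]
#' @export
sim_config <- function(n_heated_lakes = 5L,
                       n_control_lakes = 5L,
                       seasons = c("winter", "spring", "summer", "autumn"),
                       years = c(2020L, 2021L),
                       n_asvs_per_group = NULL,
                       parasite_fraction = NULL,
                       heated_richness_multiplier = 2,
                       heated_groups = c("chytrids", "aphelids"),
                       season_effects = c(winter = -0.2, spring = 0.1,
                                          summer = 0.3, autumn = 0.2),
                       host_parasite_slope = 0.5,
                       latent_sd = 0.3,
                       lake_sd = 0.15,
                       contaminant_count = 5L,
                       occupancy_baseline = 0.08,
                       n_heated_indicators = 8L,
                       n_control_indicators = 4L,
                       indicator_occupancy = c(0.9, 0.1),
                       summer_masked_year2 = TRUE,
                       autumn_extra_year1 = FALSE,
                       mean_read_count = 30,
                       seed = 1L) {
  if (is.null(n_asvs_per_group)) {
    n_asvs_per_group <- c(
      chytrids = 60L, aphelids = 35L, peronosporomycetes = 31L,
      cryptomycota = 30L, other_parasites = 24L, terrestrial_parasites = 20L,
      green_algae = 60L, diatoms = 50L, dinoflagellates = 30L,
      bystander = 110L
    )
    if (!is.null(parasite_fraction)) {
      if (!is_prob(parasite_fraction) || parasite_fraction <= 0 ||
          parasite_fraction >= 1) {
        stop_cfg("`parasite_fraction` must lie strictly in (0, 1)")
      }
      par_n <- sum(n_asvs_per_group[.parasite_groups])
      other_n <- sum(n_asvs_per_group[setdiff(names(n_asvs_per_group),
                                              c(.parasite_groups, "bystander"))])
      target_other <- round(par_n * (1 - parasite_fraction) / parasite_fraction)
      n_asvs_per_group[["bystander"]] <- max(0L, as.integer(target_other - other_n))
    }
  }
  cfg <- list(
    n_heated_lakes = n_heated_lakes, n_control_lakes = n_control_lakes,
    seasons = seasons, years = years,
    n_asvs_per_group = n_asvs_per_group,
    parasite_fraction = parasite_fraction,
    heated_richness_multiplier = heated_richness_multiplier,
    heated_groups = heated_groups,
    season_effects = season_effects,
    host_parasite_slope = host_parasite_slope,
    latent_sd = latent_sd, lake_sd = lake_sd,
    contaminant_count = contaminant_count,
    occupancy_baseline = occupancy_baseline,
    n_heated_indicators = n_heated_indicators,
    n_control_indicators = n_control_indicators,
    indicator_occupancy = indicator_occupancy,
    summer_masked_year2 = summer_masked_year2,
    autumn_extra_year1 = autumn_extra_year1,
    mean_read_count = mean_read_count,
    seed = seed
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

.parasite_groups <- c("chytrids", "aphelids", "peronosporomycetes",
                      "cryptomycota", "other_parasites",
                      "terrestrial_parasites")
.host_taxon_groups <- c("green_algae", "diatoms", "dinoflagellates")

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_heated_lakes) || cfg$n_heated_lakes < 1) {
    stop_cfg("invalid config: `n_heated_lakes` must be a positive integer")
  }
  if (!is_count(cfg$n_control_lakes) || cfg$n_control_lakes < 1) {
    stop_cfg("invalid config: `n_control_lakes` must be a positive integer")
  }
  if (length(cfg$seasons) < 1 || anyDuplicated(cfg$seasons)) {
    stop_cfg("invalid config: `seasons` must be non-empty and unique")
  }
  if (length(cfg$years) < 1 || anyDuplicated(cfg$years)) {
    stop_cfg("invalid config: `years` must be non-empty and unique")
  }
  n <- cfg$n_asvs_per_group
  if (is.null(names(n)) || any(!nzchar(names(n))) ||
      !all(vapply(n, is_count, logical(1)))) {
    stop_cfg("invalid config: `n_asvs_per_group` must be named non-negative integers")
  }
  if (sum(n) < 1) stop_cfg("invalid config: `n_asvs_per_group` sums to zero")
  if (!is.numeric(cfg$heated_richness_multiplier) ||
      cfg$heated_richness_multiplier <= 0) {
    stop_cfg("invalid config: `heated_richness_multiplier` must be > 0")
  }
  missing_seasons <- setdiff(cfg$seasons, names(cfg$season_effects))
  if (length(missing_seasons)) {
    stop_cfg("invalid config: `season_effects` lacks entries for: %s",
             paste(missing_seasons, collapse = ", "))
  }
  if (!is_prob(cfg$occupancy_baseline)) {
    stop_cfg("invalid config: `occupancy_baseline` must be in [0, 1]")
  }
  if (!is_count(cfg$contaminant_count)) {
    stop_cfg("invalid config: `contaminant_count` must be a non-negative integer")
  }
  if (length(cfg$indicator_occupancy) != 2L ||
      !all(vapply(cfg$indicator_occupancy, is_prob, logical(1)))) {
    stop_cfg("invalid config: `indicator_occupancy` must be two probabilities")
  }
  if (!is_count(cfg$n_heated_indicators) || !is_count(cfg$n_control_indicators)) {
    stop_cfg("invalid config: indicator counts must be non-negative integers")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed)) {
    stop_cfg("invalid config: `seed` must be a single integer")
  }
  invisible(cfg)
}

# host species pools keyed by host group label (map-compatible binomials)
.host_species_pool <- list(
  diatoms = c("Asterionella formosa", "Ulnaria ulna", "Fragilaria crotonensis"),
  green_algae = c("Desmodesmus armatus", "Scenedesmus obliquus",
                  "Haematococcus pluvialis", "Staurastrum paradoxum",
                  "Chlorogonium elongatum"),
  dinoflagellates = c("Peridinium cinctum", "Ceratium hirundinella"),
  crustaceans = c("Daphnia galeata", "Cyclops vicinus", "Astacus astacus"),
  fungi = c("Rhizophydium planktonicum", "Zygorhizidium affluens"),
  terrestrial_plants = c("Zea mays", "Quercus robur", "Triticum aestivum"),
  humans = c("Homo sapiens"),
  salamanders = c("Salamandra salamandra", "Triturus cristatus"),
  aquatic_plants = c("Vallisneria spiralis"),
  other_protists = c("Paramecium bursaria", "Vorticella campanula"),
  other_metazoans = c("Elliptio complanata", "Dreissena polymorpha")
)

.group_lineage <- c(
  chytrids = "Eukaryota;Fungi;Chytridiomycota;Rhizophydiales",
  aphelids = "Eukaryota;Fungi;Aphelidiomycota;Aphelidiaceae",
  cryptomycota = "Eukaryota;Fungi;Cryptomycota;Rozellida",
  peronosporomycetes = "Eukaryota;Stramenopiles;Gyrista;Peronosporomycetes;Peronosporales",
  other_parasites = "Eukaryota;Opisthokonta;Ichthyosporea;Ichthyophonida",
  terrestrial_parasites = NA,  # split between lineages below
  green_algae = "Eukaryota;Archaeplastida;Chlorophyta;Chlorophyceae",
  diatoms = "Eukaryota;Stramenopiles;Gyrista;Bacillariophyceae",
  dinoflagellates = "Eukaryota;Alveolata;Dinoflagellata;Dinophyceae",
  bystander = "Eukaryota;Alveolata;Ciliophora;Oligohymenophorea",
  contaminant = "Eukaryota;Opisthokonta;Metazoa;Arthropoda"
)

.terrestrial_lineages <- c(
  "Eukaryota;Stramenopiles;Gyrista;Peronosporomycetes;Peronosporales",
  "Eukaryota;Fungi;Ascomycota;Sordariomycetes"
)

.group_dataset <- c(
  chytrids = "fungal", aphelids = "fungal", cryptomycota = "fungal",
  peronosporomycetes = "protist", other_parasites = "protist",
  green_algae = "protist", diatoms = "protist", dinoflagellates = "protist",
  bystander = "protist", contaminant = "protist"
)

.group_genus <- list(
  chytrids = c("Rhizophydium", "Zygorhizidium", "Dangeardia", "Dinomyces"),
  aphelids = c("Aphelidium"),
  cryptomycota = c("Rozella", "Paramicrosporidium"),
  peronosporomycetes = c("Pythium", "Saprolegnia", "Aphanomyces"),
  other_parasites = c("Psorospermium", "Nematopsis"),
  terrestrial_parasites = c("Phytophthora", "Fusarium"),
  green_algae = c("Desmodesmus"), diatoms = c("Asterionella"),
  dinoflagellates = c("Peridinium"), bystander = c("Tetrahymena"),
  contaminant = c("Acarus")
)

#' Generate a synthetic survey: counts, sample metadata and ground truth
#'
#' Draws one sample per lake x season x year cell (minus masked cells) plus
#' one no-template negative control per sequencing run, an ASV count matrix
#' with the occupancy structure described in [sim_config()], per-ASV
#' sequences, a dataset-native taxonomy table, and a ground-truth table
#' recording each ASV's planned parasite status, host group, habitat
#' preference, contaminant flag and evidence-provenance plan.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `parafind_study` with elements `counts`
#'   (integer matrix, samples x ASVs), `metadata` (data.frame: sample_id,
#'   lake, lake_type, season, year, run, is_negative_control), `truth`
#'   (data.frame keyed by asv_id), `taxonomy` (asv_id, dataset, lineage,
#'   species), `sequences` (named character) and `config`.
#' @export
generate_study <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    metadata <- build_sample_metadata(config)
    truth <- build_ground_truth(config)
    counts <- draw_counts(config, metadata, truth)
    sequences <- random_sequences(truth$asv_id)
    taxonomy <- build_taxonomy(truth)
    structure(list(counts = counts, metadata = metadata, truth = truth,
                   taxonomy = taxonomy, sequences = sequences,
                   config = config),
              class = "parafind_study")
  })
}

build_sample_metadata <- function(cfg) {
  lakes <- c(sprintf("H%02d", seq_len(cfg$n_heated_lakes)),
             sprintf("C%02d", seq_len(cfg$n_control_lakes)))
  lake_type <- rep(c("heated", "control"),
                   c(cfg$n_heated_lakes, cfg$n_control_lakes))
  grid <- expand.grid(lake = lakes, season = cfg$seasons, year = cfg$years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (isTRUE(cfg$summer_masked_year2) && length(cfg$years) >= 2) {
    grid <- grid[!(grid$season == "summer" & grid$year == cfg$years[2]), ]
  }
  grid$event <- 1L
  if (isTRUE(cfg$autumn_extra_year1)) {
    extra <- grid[grid$season == "autumn" & grid$year == cfg$years[1], ]
    if (nrow(extra)) {
      extra$event <- 2L
      grid <- rbind(grid, extra)
    }
  }
  grid <- grid[order(match(grid$lake, lakes), match(grid$year, cfg$years),
                     match(grid$season, cfg$seasons), grid$event), ]
  md <- data.frame(
    sample_id = ifelse(grid$event == 1L,
                       paste(grid$lake, grid$season, grid$year, sep = "_"),
                       paste(grid$lake, grid$season, grid$year, "b", sep = "_")),
    lake = grid$lake,
    lake_type = lake_type[match(grid$lake, lakes)],
    season = grid$season,
    year = grid$year,
    run = paste0("run", match(grid$year, cfg$years)),
    is_negative_control = FALSE,
    stringsAsFactors = FALSE
  )
  runs <- paste0("run", seq_along(cfg$years))
  neg <- data.frame(
    sample_id = paste0("NEG_", runs), lake = NA_character_,
    lake_type = NA_character_, season = NA_character_,
    year = cfg$years, run = runs, is_negative_control = TRUE,
    stringsAsFactors = FALSE
  )
  out <- rbind(md, neg)
  rownames(out) <- NULL
  out
}

build_ground_truth <- function(cfg) {
  n <- cfg$n_asvs_per_group
  groups <- rep(names(n), n)
  if (cfg$contaminant_count > 0) {
    groups <- c(groups, rep("contaminant", cfg$contaminant_count))
  }
  total <- length(groups)
  asv_id <- sprintf("ASV_%04d", seq_len(total))
  is_parasite <- groups %in% .parasite_groups
  is_contaminant <- groups == "contaminant"

  host_group <- rep(NA_character_, total)
  for (i in seq_len(total)) {
    host_group[i] <- switch(groups[i],
      chytrids = sample(c("diatoms", "green_algae", "dinoflagellates"), 1,
                        prob = c(0.5, 0.35, 0.15)),
      aphelids = "green_algae",
      peronosporomycetes = sample(c("green_algae", "crustaceans",
                                    "aquatic_plants"), 1,
                                  prob = c(0.5, 0.3, 0.2)),
      cryptomycota = "fungi",
      other_parasites = sample(c("crustaceans", "other_protists",
                                 "other_metazoans"), 1),
      terrestrial_parasites = sample(c("terrestrial_plants", "humans"), 1,
                                     prob = c(0.8, 0.2)),
      NA_character_)
  }
  # a small fixed share of chytrids parasitise salamanders (amphibian hosts
  # whose richness the survey does not measure)
  chy <- which(groups == "chytrids")
  if (length(chy)) {
    n_sal <- max(1L, ceiling(0.02 * length(chy)))
    host_group[chy[seq_len(n_sal)]] <- "salamanders"
  }

  provenance <- rep("none", total)
  par_idx <- which(is_parasite)
  if (length(par_idx)) {
    provenance[par_idx] <- sample(c("both", "literature_only", "genbank_only"),
                                  length(par_idx), replace = TRUE,
                                  prob = c(0.25, 0.25, 0.5))
  }

  route <- rep(NA_character_, total)
  nonpar <- which(!is_parasite)
  if (length(nonpar)) {
    route[nonpar] <- sample(c("no_hit", "below_threshold", "abiotic",
                              "nonliving", "symbiont"),
                            length(nonpar), replace = TRUE,
                            prob = c(0.35, 0.15, 0.25, 0.10, 0.15))
  }

  habitat <- rep("none", total)
  eligible <- which(is_parasite & groups != "terrestrial_parasites")
  want <- cfg$n_heated_indicators + cfg$n_control_indicators
  if (want > length(eligible)) {
    stop_cfg("invalid config: fewer eligible parasite ASVs (%d) than planted indicators (%d)",
             length(eligible), want)
  }
  picked <- sample(eligible, want)
  habitat[picked[seq_len(cfg$n_heated_indicators)]] <- "heated"
  if (cfg$n_control_indicators > 0) {
    habitat[picked[cfg$n_heated_indicators + seq_len(cfg$n_control_indicators)]] <- "control"
  }

  lineage <- unname(.group_lineage[groups])
  terr <- which(groups == "terrestrial_parasites")
  if (length(terr)) {
    lineage[terr] <- rep(.terrestrial_lineages, length.out = length(terr))
  }
  dataset <- unname(.group_dataset[groups])
  dataset[terr] <- ifelse(grepl("Peronosporomycetes", lineage[terr]),
                          "protist", "fungal")

  data.frame(asv_id = asv_id, group = groups, dataset = dataset,
             lineage = lineage, is_parasite = is_parasite,
             host_group = host_group, habitat_preference = habitat,
             is_contaminant = is_contaminant,
             provenance_planned = provenance,
             nonparasite_route = route,
             stringsAsFactors = FALSE)
}

draw_counts <- function(cfg, metadata, truth) {
  lake_md <- metadata[!metadata$is_negative_control, ]
  n_s <- nrow(lake_md)
  n_a <- nrow(truth)

  lakes <- unique(lake_md$lake)
  lake_off <- stats::rnorm(length(lakes), 0, cfg$lake_sd)
  names(lake_off) <- lakes
  latent <- stats::rnorm(n_s, 0, cfg$latent_sd)

  base <- cfg$occupancy_baseline *
    exp(unname(cfg$season_effects[lake_md$season]) +
          lake_off[lake_md$lake])

  p <- matrix(0, n_s, n_a, dimnames = list(lake_md$sample_id, truth$asv_id))
  heated <- lake_md$lake_type == "heated"
  for (j in seq_len(n_a)) {
    pj <- base
    grp <- truth$group[j]
    if (grp %in% cfg$heated_groups) {
      pj[heated] <- pj[heated] * cfg$heated_richness_multiplier
    }
    if (grp %in% .host_taxon_groups) pj <- pj * exp(latent)
    if (grp == "chytrids") pj <- pj * exp(cfg$host_parasite_slope * latent)
    if (truth$habitat_preference[j] != "none") {
      pref <- lake_md$lake_type == truth$habitat_preference[j]
      pj[pref] <- cfg$indicator_occupancy[1]
      pj[!pref] <- cfg$indicator_occupancy[2]
    }
    if (truth$is_contaminant[j]) {
      contam_run <- contaminant_run(cfg, which(truth$is_contaminant) == j)
      pj[] <- 0
      pj[lake_md$run == contam_run] <- 0.3
    }
    p[, j] <- pmin(pj, 0.95)
  }

  presence <- matrix(stats::rbinom(n_s * n_a, 1, as.vector(p)), n_s, n_a)
  lam <- max(cfg$mean_read_count - 1, 0)
  reads <- presence * (1L + stats::rpois(n_s * n_a, lam))
  contam_cols <- which(truth$is_contaminant)
  if (length(contam_cols)) {
    # contaminants carry only trace read counts
    for (j in contam_cols) {
      hits <- presence[, j] == 1
      reads[hits, j] <- 1L + stats::rpois(sum(hits), 2)
    }
  }
  dimnames(reads) <- list(lake_md$sample_id, truth$asv_id)

  neg_md <- metadata[metadata$is_negative_control, ]
  neg <- matrix(0L, nrow(neg_md), n_a,
                dimnames = list(neg_md$sample_id, truth$asv_id))
  if (length(contam_cols)) {
    runs_of <- vapply(seq_along(contam_cols), function(k)
      contaminant_run(cfg, k == seq_along(contam_cols)), character(1))
    for (k in seq_along(contam_cols)) {
      row <- which(neg_md$run == runs_of[k])
      neg[row, contam_cols[k]] <- 1L + stats::rpois(1, 3)
    }
  }
  out <- rbind(reads, neg)
  storage.mode(out) <- "integer"
  out[match(metadata$sample_id, rownames(out)), , drop = FALSE]
}

# k-th contaminant alternates between sequencing runs
contaminant_run <- function(cfg, is_k) {
  k <- which(is_k)
  runs <- paste0("run", seq_along(cfg$years))
  runs[((k - 1L) %% length(runs)) + 1L]
}

random_sequences <- function(asv_ids, len = 250L) {
  seqs <- vapply(asv_ids, function(id) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- asv_ids
  seqs
}

build_taxonomy <- function(truth) {
  data.frame(asv_id = truth$asv_id, dataset = truth$dataset,
             lineage = truth$lineage, species = NA_character_,
             stringsAsFactors = FALSE)
}

#' Generate reference records, literature evidence and a similarity-hit table
#'
#' Emits, for every ASV in the ground truth, the artefacts the classifier
#' consumes: reference records (accession, lineage, host strings, sequence),
#' literature-evidence rows (species, parasitism flag, hosts), and a tabular
#' similarity-hit file in `outfmt 6` column order plus a query-cover column.
#' Hits and record metadata are constructed so that deterministic
#' classification recovers the planned parasite status and provenance of
#' every ASV: qualifying hits have identity >= 90 and 100% cover; ASVs
#' planned for literature evidence get species-resolvable hits (> 98%
#' identity) or a dataset-native species assignment; planned non-parasites
#' follow their planned route (no hit, sub-threshold hit, abiotic,
#' non-living or symbiont-context record).
#'
#' @param truth Ground-truth table from [generate_study()] (or a full
#'   `parafind_study`, whose truth/taxonomy/sequences are used).
#' @param config The same [sim_config()] used to generate the study.
#' @return List with `records`, `literature`, `hits` data.frames and an
#'   updated `taxonomy` table (dataset-native species filled in where
#'   planned).
#' @export
generate_reference_and_hits <- function(truth, config) {
  study <- NULL
  if (inherits(truth, "parafind_study")) {
    study <- truth
    truth <- study$truth
  }
  if (!nrow(truth)) stop_cfg("ground truth is empty")
  validate_sim_config(config)
  taxonomy <- if (!is.null(study)) study$taxonomy else build_taxonomy(truth)
  sequences <- if (!is.null(study)) study$sequences else NULL

  with_seed(config$seed + 104729L, {
    recs <- list(); lits <- list(); hits <- list()
    lit_native <- 0L
    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      plan <- tr$provenance_planned
      route <- tr$nonparasite_route
      acc <- sprintf("REF_%04d", i)
      genus <- sample(.group_genus[[tr$group]], 1)
      species <- sprintf("%s synthetica%d", genus, i)
      lineage_sp <- paste(tr$lineage, genus, species, sep = ";")
      hosts <- character(0)
      note <- ""
      emit_hit <- TRUE
      identity <- NA_real_
      cover <- 100

      if (plan %in% c("both", "genbank_only", "literature_only")) {
        if (plan == "genbank_only") {
          identity <- round(stats::runif(1, 90.0, 97.9), 2)
        } else {
          identity <- round(stats::runif(1, 98.05, 99.9), 2)
        }
        host_pool <- .host_species_pool[[tr$host_group]]
        hosts <- sample(host_pool, min(length(host_pool),
                                       sample(1:2, 1)))
        if (plan == "literature_only") {
          hosts <- character(0)  # record carries no host metadata
          lit_native <- lit_native + 1L
          if (lit_native %% 3L == 0L) {
            # dataset-native species assignment, no similarity hit at all
            emit_hit <- FALSE
            taxonomy$species[taxonomy$asv_id == tr$asv_id] <- species
          }
        }
        if (plan %in% c("both", "literature_only")) {
          lit_hosts <- sample(.host_species_pool[[tr$host_group]], 1)
          lits[[length(lits) + 1L]] <- data.frame(
            species_name = species, is_parasite = TRUE,
            hosts = collapse_multi(lit_hosts),
            source = sprintf("synthetic-literature-%04d", i),
            stringsAsFactors = FALSE)
        }
      } else {
        switch(route,
          no_hit = { emit_hit <- FALSE },
          below_threshold = {
            if (stats::runif(1) < 0.5) {
              identity <- round(stats::runif(1, 70, 89.4), 2)
            } else {
              identity <- round(stats::runif(1, 91, 99), 2)
              cover <- round(stats::runif(1, 80, 99), 1)
            }
            hosts <- sample(.host_species_pool$crustaceans, 1)
          },
          abiotic = {
            identity <- round(stats::runif(1, 90, 99.9), 2)
            hosts <- sample(c("lake water", "soil", "mud sediment",
                              "freshwater sediment"), 1)
          },
          nonliving = {
            identity <- round(stats::runif(1, 90, 99.9), 2)
            hosts <- sample(c("decaying log", "fallen branch", "dead wood"), 1)
          },
          symbiont = {
            identity <- round(stats::runif(1, 90, 99.9), 2)
            if (stats::runif(1) < 0.5) {
              hosts <- "algal endosymbiont of Paramecium bursaria"
            } else {
              hosts <- sample(.host_species_pool$green_algae, 1)
              note <- "isolated from pathobiome of diseased host; lichen-associated culture"
            }
          })
      }

      seq_i <- if (!is.null(sequences)) sequences[[tr$asv_id]] else
        paste(sample(c("A", "C", "G", "T"), 250, TRUE), collapse = "")
      recs[[length(recs) + 1L]] <- data.frame(
        accession = acc, lineage = lineage_sp, species = species,
        marker = sample(c("18S", "28S", "ITS"), 1),
        hosts = collapse_multi(hosts), source_note = note,
        sequence = seq_i, stringsAsFactors = FALSE)

      if (emit_hit) {
        top_bit <- round(stats::runif(1, 420, 500), 1)
        hit_rows <- data.frame(
          qseqid = tr$asv_id, sseqid = acc, pident = identity,
          length = 250L, mismatch = round(250 * (100 - identity) / 100),
          gapopen = 0L, qstart = 1L, qend = 250L, sstart = 1L, send = 250L,
          evalue = 10^(-stats::runif(1, 80, 140)), bitscore = top_bit,
          qcovs = cover, stringsAsFactors = FALSE)
        # decoys only under a qualifying top hit, so sub-threshold plans
        # leave no qualifying hit at all
        n_decoy <- if (identity >= 90 && cover >= 100) sample(0:3, 1) else 0L
        if (n_decoy > 0) {
          decoys <- data.frame(
            qseqid = tr$asv_id,
            sseqid = sprintf("DEC_%04d_%d", i, seq_len(n_decoy)),
            pident = round(stats::runif(n_decoy, 90, identity), 2),
            length = 250L, mismatch = 5L, gapopen = 0L, qstart = 1L,
            qend = 250L, sstart = 1L, send = 250L,
            evalue = 10^(-stats::runif(n_decoy, 40, 79)),
            bitscore = round(top_bit - stats::runif(n_decoy, 5, 100), 1),
            qcovs = 100, stringsAsFactors = FALSE)
          hit_rows <- rbind(hit_rows, decoys)
        }
        hits[[length(hits) + 1L]] <- hit_rows
      }
    }
    literature <- if (length(lits)) do.call(rbind, lits) else
      data.frame(species_name = character(0), is_parasite = logical(0),
                 hosts = character(0), source = character(0))
    list(records = do.call(rbind, recs),
         literature = literature,
         hits = if (length(hits)) do.call(rbind, hits) else
           empty_hit_table(),
         taxonomy = taxonomy)
  })
}

#' One-call synthetic study with all classifier inputs
#'
#' Convenience wrapper: [generate_study()] plus
#' [generate_reference_and_hits()] under one configuration.
#'
#' @param seed Integer seed.
#' @param config Optional [sim_config()]; when given, `seed` is ignored.
#' @return A `parafind_study` list additionally carrying `records`,
#'   `literature` and `hits`.
#' @export
demo_study <- function(seed = 1L, config = NULL) {
  cfg <- config %||% sim_config(seed = seed)
  study <- generate_study(cfg)
  aux <- generate_reference_and_hits(study, cfg)
  study$records <- aux$records
  study$literature <- aux$literature
  study$hits <- aux$hits
  study$taxonomy <- aux$taxonomy
  study
}

#' @export
print.parafind_study <- function(x, ...) {
  md <- x$metadata
  cat("Synthetic eDNA survey\n")
  cat(sprintf("  %d lake samples + %d negative controls, %d ASVs\n",
              sum(!md$is_negative_control), sum(md$is_negative_control),
              ncol(x$counts)))
  cat(sprintf("  parasites planned: %d of %d ASVs (%d contaminants)\n",
              sum(x$truth$is_parasite), nrow(x$truth),
              sum(x$truth$is_contaminant)))
  invisible(x)
}
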