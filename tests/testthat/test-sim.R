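test_that("sampling design yields one sample per unmasked cell plus controls", {
  cfg <- sim_config(seed = 5)
  study <- generate_study(cfg)
  md <- study$metadata
  # 10 lakes x (4 + 4 - 1 masked summer) season-year cells = 70 lake samples
  expect_equal(sum(!md$is_negative_control), 70L)
  expect_equal(sum(md$is_negative_control), 2L)  # one control per run
  expect_equal(sum(md$season == "summer" & md$year == 2021, na.rm = TRUE), 0L)
  # per lake type and season, sample sizes follow the masked design
  lt <- md[!md$is_negative_control, ]
  tab <- table(lt$season)[c("winter", "spring", "summer", "autumn")]
  expect_equal(unname(as.integer(tab)), c(20L, 20L, 10L, 20L))
  # the design variant with a second autumn sampling event in year 1
  cfg2 <- sim_config(seed = 5, autumn_extra_year1 = TRUE)
  md2 <- generate_study(cfg2)$metadata
  expect_equal(sum(!md2$is_negative_control), 80L)
})

test_that("identical configurations are byte-identical; different seeds differ", {
  a <- generate_study(sim_config(seed = 11))
  b <- generate_study(sim_config(seed = 11))
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(a$sequences, b$sequences)
  c <- generate_study(sim_config(seed = 12))
  expect_false(identical(a$counts, c$counts))
  # generation does not disturb the caller's RNG stream
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(generate_study(sim_config(seed = 1))); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("contaminants are planted in negative controls, exactly as counted", {
  study <- generate_study(sim_config(contaminant_count = 3L, seed = 2))
  truth <- study$truth
  expect_equal(sum(truth$is_contaminant), 3L)
  neg <- study$counts[study$metadata$sample_id[study$metadata$is_negative_control], ,
                      drop = FALSE]
  for (id in truth$asv_id[truth$is_contaminant]) {
    expect_gt(sum(neg[, id]), 0)
  }
  # non-contaminant ASVs never appear in controls
  clean <- truth$asv_id[!truth$is_contaminant]
  expect_equal(sum(neg[, clean]), 0L)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(n_heated_lakes = 0), "n_heated_lakes")
  expect_error(sim_config(heated_richness_multiplier = -1),
               "heated_richness_multiplier")
  expect_error(sim_config(occupancy_baseline = 1.5), "occupancy_baseline")
  expect_error(sim_config(season_effects = c(winter = 0)), "season_effects")
  expect_error(sim_config(seasons = character(0)), "seasons")
  expect_error(sim_config(parasite_fraction = 1.2), "parasite_fraction")
})

test_that("null configuration injects no lake-type difference in focal richness", {
  # Monte-Carlo under the null: multiplier 1, no season effects, no coupling
  n_rep <- 60
  diffs <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    cfg <- sim_config(heated_richness_multiplier = 1,
                      season_effects = c(winter = 0, spring = 0, summer = 0,
                                         autumn = 0),
                      host_parasite_slope = 0, latent_sd = 0, lake_sd = 0,
                      n_heated_indicators = 0L, n_control_indicators = 0L,
                      seed = 1000 + i)
    study <- generate_study(cfg)
    md <- study$metadata[!study$metadata$is_negative_control, ]
    foc <- study$truth$asv_id[study$truth$group == "chytrids"]
    rich <- rowSums(study$counts[md$sample_id, foc] >= 1)
    heated <- md$lake_type == "heated"
    diffs[i] <- mean(rich[heated]) - mean(rich[!heated])
  }
  # the replicate-mean difference stays within 2 standard errors of zero
  expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(n_rep))
})

test_that("reference and hit generation follows the evidence plan", {
  cfg <- sim_config(seed = 21)
  study <- demo_study(config = cfg)
  truth <- study$truth
  hits <- study$hits
  recs <- study$records

  # planned no-hit ASVs have zero hit rows
  none <- truth$asv_id[!is.na(truth$nonparasite_route) &
                         truth$nonparasite_route == "no_hit"]
  expect_equal(sum(hits$qseqid %in% none), 0L)

  # qualifying hits for planned parasites; top hit record matches the plan
  ranked <- process_hits(hits)
  best <- best_hits(ranked)
  gb <- truth[truth$provenance_planned == "genbank_only", ]
  for (i in seq_len(min(10, nrow(gb)))) {
    b <- best[best$qseqid == gb$asv_id[i], ]
    expect_equal(nrow(b), 1L)
    expect_gte(b$pident, 90)
    rec <- recs[recs$accession == b$sseqid, ]
    expect_true(nzchar(rec$hosts))
    expect_false(gb$asv_id[i] %in% study$literature$species_name)
  }

  # abiotic-route ASVs point at abiotic-lexicon host entries
  ab <- truth$asv_id[!is.na(truth$nonparasite_route) &
                       truth$nonparasite_route == "abiotic"]
  ab_best <- best[best$qseqid %in% ab, ]
  ab_hosts <- recs$hosts[match(ab_best$sseqid, recs$accession)]
  expect_true(all(vapply(ab_hosts, classify_host_string, character(1)) ==
                    "abiotic"))

  # below-threshold routes leave no qualifying hit
  bt <- truth$asv_id[!is.na(truth$nonparasite_route) &
                       truth$nonparasite_route == "below_threshold"]
  expect_equal(sum(best$qseqid %in% bt), 0L)
})
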