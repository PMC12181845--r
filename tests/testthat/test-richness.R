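make_calls <- function(asv_id, status, host_groups) {
  data.frame(asv_id = asv_id, status = status, host_groups = host_groups,
             stringsAsFactors = FALSE)
}

test_that("focal-group selection applies dataset and terrestrial-host rules", {
  calls <- make_calls(
    c("g1", "g2", "f1", "f2", "f3", "p1"),
    rep("parasite", 6),
    c("terrestrial_plants",            # Gyrista with terrestrial host: out
      "green_algae",                   # Peronosporomycete, aquatic: in
      "diatoms",                       # fungal-dataset chytrid: in
      "salamanders",                   # chytrid with salamander host: flagged
      "terrestrial_plants|humans",     # exclusively terrestrial: out
      "diatoms"))                      # protist-dataset chytrid: not fungal
  taxa <- data.frame(
    asv_id = c("g1", "g2", "f1", "f2", "f3", "p1"),
    lineage = c("Eukaryota;Gyrista;Peronosporomycetes",
                "Eukaryota;Gyrista;Peronosporomycetes",
                "Eukaryota;Fungi;Chytridiomycota",
                "Eukaryota;Fungi;Chytridiomycota",
                "Eukaryota;Fungi;Chytridiomycota",
                "Eukaryota;Fungi;Chytridiomycota"),
    dataset = c("protist", "protist", "fungal", "fungal", "fungal", "protist"),
    stringsAsFactors = FALSE)
  out <- select_focal_groups(calls, taxa)
  expect_setequal(out$asv_id, c("g2", "f1", "f2"))
  expect_equal(out$group[out$asv_id == "g2"], "peronosporomycetes")
  expect_true(out$exclude_from_host_corr[out$asv_id == "f2"])
  expect_false(out$exclude_from_host_corr[out$asv_id == "f1"])
  expect_error(select_focal_groups(calls, taxa,
                                   rules = data.frame(taxon = "x")),
               "columns")
})

test_that("richness recounts distinct present ASVs and matches planted truth", {
  study <- generate_study(sim_config(seed = 17))
  md <- study$metadata[!study$metadata$is_negative_control, ]
  counts <- study$counts[md$sample_id, ]
  truth <- study$truth
  assignment <- data.frame(asv_id = truth$asv_id[truth$group == "chytrids"],
                           group = "chytrids", stringsAsFactors = FALSE)
  host_ids <- truth$asv_id[truth$group %in% c("green_algae", "diatoms",
                                              "dinoflagellates")]
  tab <- compute_richness(counts, assignment, study$metadata,
                          host_asvs = host_ids)
  # oracle: direct recount from the raw matrix
  expect_equal(tab$chytrids,
               unname(rowSums(counts[, assignment$asv_id] >= 1)))
  expect_equal(tab$host_richness, unname(rowSums(counts[, host_ids] >= 1)))
  expect_true(all(tab$chytrids <= nrow(assignment)))
  # all-zero sample yields zero richness
  z <- counts
  z[1, ] <- 0L
  tabz <- compute_richness(z, assignment, study$metadata)
  expect_equal(tabz$chytrids[1], 0L)
  # unknown samples are reported by id
  bad <- counts
  rownames(bad)[1] <- "mystery"
  expect_error(compute_richness(bad, assignment, study$metadata), "mystery")
})

test_that("intercept-only Poisson fit recovers the log mean in closed form", {
  y <- c(2L, 4L, 6L)
  fit <- glm(y ~ 1, family = poisson())
  expect_equal(unname(coef(fit)), log(4), tolerance = 1e-8)
  # and the package's deviance matches the first-principles formula
  expect_equal(deviance(fit), poisson_dev_oracle(y, fitted(fit)),
               tolerance = 1e-10)
})

test_that("model fits agree with an independent IRLS oracle", {
  set.seed(123)
  for (rep in 1:20) {
    n <- 60
    dat <- data.frame(
      lake_type = factor(sample(c("heated", "control"), n, TRUE)),
      season = factor(sample(c("winter", "spring", "summer", "autumn"),
                             n, TRUE)),
      lake = "L1", run = "r1", year = 2020L)
    eta <- 1 + 0.5 * (dat$lake_type == "heated") +
      0.3 * (dat$season == "summer")
    dat$sample_id <- paste0("S", 1:n)
    dat$grp <- rpois(n, exp(eta))
    fit <- fit_richness_model(dat, "grp")
    X <- model.matrix(~ lake_type * season, dat,
                      contrasts.arg = list(lake_type = "contr.sum",
                                           season = "contr.sum"))
    oracle <- irls_poisson(X, dat$grp)
    expect_equal(unname(coef(fit)), unname(oracle$coef), tolerance = 1e-6)
    expect_equal(fit$deviance, oracle$deviance, tolerance = 1e-6)
    expect_lte(fit$deviance, fit$null_deviance)
  }
})

test_that("Type-III interaction test is invariant to factor relabelling", {
  set.seed(9)
  dat <- data.frame(
    lake_type = factor(rep(c("heated", "control"), each = 30)),
    season = factor(rep(c("winter", "spring", "summer"), 20)),
    lake = "L", run = "r", year = 2020L, sample_id = paste0("S", 1:60))
  dat$grp <- rpois(60, 5)
  f1 <- fit_richness_model(dat, "grp")
  dat2 <- dat
  dat2$season <- factor(dat2$season,
                        levels = c("summer", "winter", "spring"))
  dat2$lake_type <- factor(dat2$lake_type, levels = c("heated", "control"))
  f2 <- fit_richness_model(dat2, "grp")
  get_term <- function(f, t) f$anova[f$anova$term == t, c("chisq", "p_value")]
  expect_equal(get_term(f1, "lake_type:season"),
               get_term(f2, "lake_type:season"), tolerance = 1e-8)
  expect_equal(get_term(f1, "lake_type"), get_term(f2, "lake_type"),
               tolerance = 1e-8)
})

test_that("mixed-effects requests fall back to fixed effects when singular", {
  set.seed(5)
  dat <- data.frame(
    lake_type = factor(rep(c("heated", "control"), each = 20)),
    season = factor(rep(c("winter", "spring"), 20)),
    lake = rep(sprintf("L%d", 1:4), each = 10),
    run = "r1", year = 2020L, sample_id = paste0("S", 1:40))
  dat$grp <- rpois(40, 4)  # no lake variance: singular random intercept
  fit <- fit_richness_model(dat, "grp", random_terms = c("lake", "run"))
  expect_equal(fit$meta$backend, "glm")
  expect_true(fit$meta$reduced_random_effects)
  expect_s3_class(fit$fit, "glm")
})

test_that("partial R-squared equals the deviance ratio computed from scratch", {
  set.seed(31)
  dat <- data.frame(x = rnorm(50), season = factor(rep(c("a", "b"), 25)))
  dat$y <- rpois(50, exp(0.5 + 0.7 * dat$x))
  full <- glm(y ~ x + season, dat, family = poisson())
  no_x <- glm(y ~ season, dat, family = poisson())
  r2 <- partial_r2(full, no_x)
  # brute-force deviance evaluation from first principles
  d_full <- poisson_dev_oracle(dat$y, fitted(full))
  d_red <- poisson_dev_oracle(dat$y, fitted(no_x))
  expect_equal(r2, (d_red - d_full) / d_red, tolerance = 1e-10)
  expect_gte(r2, 0)
  expect_lte(r2, 1)
  # a no-effect term at large n gives a near-zero partial R2
  dat$noise <- rnorm(50)
  with_noise <- glm(y ~ x + season + noise, dat, family = poisson())
  expect_lt(partial_r2(with_noise, full), 0.05)
  # non-nested pairs are rejected
  other <- glm(y ~ x, dat, family = poisson())
  expect_error(partial_r2(with_noise, other), "exactly one term")
})

test_that("saturated full model gives partial R2 of one", {
  # two-point data fitted exactly by its own factor
  dat <- data.frame(g = factor(c("a", "a", "b", "b")), y = c(2L, 2L, 7L, 7L))
  full <- glm(y ~ g, dat, family = poisson())
  reduced <- glm(y ~ 1, dat, family = poisson())
  expect_equal(partial_r2(full, reduced), 1, tolerance = 1e-6)
})

test_that("the heated/control contrast recovers an injected multiplier", {
  rec <- multiplier_recovery(multiplier = 2, n_sims = 25, seed = 4000)
  expect_gte(mean(rec$covered), 0.8)
  expect_lt(abs(mean(rec$estimate) - log(2)), 0.1)
})
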