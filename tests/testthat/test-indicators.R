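test_that("presence/absence conversion binarizes and is idempotent", {
  m <- matrix(c(0, 1, 37, 0, 0, 0), 2, 3)
  pa <- to_presence_absence(m)
  expect_equal(as.vector(pa), c(0, 1, 1, 0, 0, 0))
  expect_equal(to_presence_absence(pa), pa)
})

test_that("association statistic is the group occurrence frequency", {
  presence <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  groups <- rep(c("heated", "control"), each = 5)
  st <- association_statistic(presence, groups)
  expect_equal(unname(st$stat[c("heated", "control")]), c(0.8, 0.0))
  expect_equal(st$preferred, "heated")
  expect_false(st$tie)
  st2 <- association_statistic(rep(1, 10), groups)
  expect_true(st2$tie)
  expect_equal(unname(st2$stat), c(1, 1))
  expect_error(association_statistic(presence, rep("heated", 10)), "non-empty")
})

test_that("tiny designs are enumerated exhaustively and match brute force", {
  # 4 samples, 2 + 2: 6 distinct labelings
  counts <- matrix(c(1, 1, 0, 0,
                     1, 0, 1, 0), 4, 2,
                   dimnames = list(paste0("S", 1:4), c("X", "Y")))
  groups <- c("heated", "heated", "control", "control")
  expect_message(res <- indicator_analysis(counts, groups, n_perm = 999),
                 "exhaustively")
  expect_equal(res$method, rep("exhaustive", 2))
  expect_equal(res$n_perm, rep(6L, 2))
  # brute force over all 6 labelings
  brute_p <- function(pres) {
    labelings <- combn(4, 2)
    obs <- max(mean(pres[1:2]), mean(pres[3:4]))
    stats <- apply(labelings, 2, function(ix) {
      g1 <- seq_len(4) %in% ix
      max(mean(pres[g1]), mean(pres[!g1]))
    })
    mean(stats >= obs)
  }
  expect_equal(res$p_perm[1], brute_p(c(1, 1, 0, 0)))
  expect_equal(res$p_perm[2], brute_p(c(1, 0, 1, 0)))
})

test_that("sampled permutation p-values follow the add-one convention", {
  set.seed(4)
  n <- 40
  counts <- cbind(ind = c(rep(1L, 20), rep(0L, 20)),
                  flat = rep(1L, n),
                  absent = rep(0L, n),
                  mod = as.integer(c(rbinom(20, 1, 0.7), rbinom(20, 1, 0.4))))
  rownames(counts) <- paste0("S", 1:n)
  groups <- rep(c("heated", "control"), each = 20)
  res <- indicator_analysis(counts, groups, n_perm = 999, seed = 8)
  # perfectly separated ASV: only the identity-like permutations reach the
  # observed statistic; p is bounded below by 1/(1+n_perm)
  expect_gte(res$p_perm[1], 1 / 1000)
  expect_lt(res$p_perm[1], 0.01)
  # constant-presence ASV is permutation-invariant: p = 1
  expect_equal(res$p_perm[2], 1)
  # absent ASV excluded from testing
  expect_false(res$tested[3])
  expect_equal(res$p_perm[3], 1)
  # determinism and seed sensitivity: Monte-Carlo noise is O(n_perm^-1/2)
  res2 <- indicator_analysis(counts, groups, n_perm = 999, seed = 8)
  expect_identical(res$p_perm, res2$p_perm)
  res3 <- indicator_analysis(counts, groups, n_perm = 999, seed = 9)
  expect_false(identical(res$p_perm[4], res3$p_perm[4]))
  expect_lt(abs(res$p_perm[4] - res3$p_perm[4]), 4 / sqrt(999))
})

test_that("Sidak correction matches direct evaluation and dominance bounds", {
  ps <- c(0, 1e-6, 1e-4, 0.01, 0.05, 0.2, 0.5, 0.9, 1)
  ks <- c(1L, 2L, 5L, 20L, 100L)
  for (k in ks) {
    direct <- 1 - (1 - ps)^k
    expect_equal(sidak_correct(ps, k), pmin(1, direct), tolerance = 1e-12)
    # dominance: raw p <= Sidak <= Bonferroni
    expect_true(all(sidak_correct(ps, k) >= ps - 1e-15))
    expect_true(all(sidak_correct(ps, k) <= pmin(1, k * ps) + 1e-12))
  }
  expect_equal(sidak_correct(0.05, 2), 0.0975)
  expect_equal(sidak_correct(0.3, 1), 0.3)
  expect_equal(sidak_correct(0, 1000L), 0)
})

test_that("indicator calling separates significance from the display filter", {
  res <- data.frame(asv_id = c("a", "b", "c"),
                    p_sidak = c(0.049, 0.051, 0.001),
                    prevalence = c(0.5, 0.5, 0.15),
                    tested = TRUE, stringsAsFactors = FALSE)
  called <- call_indicators(res, alpha = 0.05)
  expect_setequal(called$asv_id, c("a", "c"))
  displayed <- call_indicators(res, alpha = 0.05, min_prevalence = 0.20)
  # c stays significant but is excluded from display by prevalence
  expect_equal(displayed$asv_id, "a")
})

test_that("planted habitat preference is detected with high power", {
  # occupancy 0.9 in the preferred habitat vs 0.1, 35 + 35 samples
  detected <- logical(40)
  groups <- rep(c("heated", "control"), each = 35)
  for (i in seq_along(detected)) {
    set.seed(300 + i)
    pres <- c(rbinom(35, 1, 0.9), rbinom(35, 1, 0.1))
    counts <- cbind(ind = as.integer(pres))
    rownames(counts) <- paste0("S", 1:70)
    res <- indicator_analysis(counts, groups, n_perm = 999, seed = i)
    detected[i] <- res$p_sidak[1] < 0.05 & res$preferred_group[1] == "heated"
  }
  expect_gte(mean(detected), 0.95)
})

test_that("Sidak dominance holds on real analysis output", {
  study <- generate_study(sim_config(seed = 33))
  md <- study$metadata[!study$metadata$is_negative_control, ]
  counts <- study$counts[md$sample_id, 1:100]
  res <- indicator_analysis(counts, md$lake_type, n_perm = 199, seed = 1)
  expect_true(all(res$p_sidak >= res$p_perm))
  expect_true(all(res$p_perm > 0 & res$p_perm <= 1))
  expect_true(all(res$p_sidak <= pmin(1, 2 * res$p_perm) + 1e-12))
})
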