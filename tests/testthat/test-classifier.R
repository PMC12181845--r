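test_that("host strings classify as live, abiotic, non-living or symbiont context", {
  expect_equal(classify_host_string("mud sediment"), "abiotic")
  expect_equal(classify_host_string("decaying log"), "nonliving")
  expect_equal(classify_host_string("Daphnia galeata"), "live_host")
  expect_equal(classify_host_string("algal endosymbiont of Paramecium"),
               "symbiont_context")
  expect_equal(classify_host_string("  Lake WATER "), "abiotic")
  expect_equal(classify_host_string(""), "abiotic")
  expect_error(lexicons(abiotic = c("water"), nonliving = c("water"),
                        symbiont = "x"), "disjoint")
})

test_that("species assignment requires strict >98% identity and species rank", {
  rec <- make_record("R1", species = "Zygorhizidium planktonicum")
  expect_equal(assign_species(make_hit("Q", "R1", 98.5, 400), rec),
               "Zygorhizidium planktonicum")
  expect_true(is.na(assign_species(make_hit("Q", "R1", 98.0, 400), rec)))
  expect_true(is.na(assign_species(make_hit("Q", "R1", 95, 400), rec)))
  norank <- make_record("R2")
  expect_true(is.na(assign_species(make_hit("Q", "R2", 99.9, 400), norank)))
  expect_true(is.na(assign_species(NULL, rec)))
})

test_that("the classifier reproduces the expected call table on the rule-branch fixture", {
  fx <- classifier_fixture()
  calls <- classify_asvs(fx$hits, fx$records, fx$literature,
                         asv_ids = fx$asv_ids, taxonomy = fx$taxonomy)
  expect_equal(calls$asv_id, fx$expected$asv_id)
  expect_equal(calls$status, fx$expected$status)
  expect_equal(calls$provenance, fx$expected$provenance)
  expect_equal(calls$exclusion_reason, fx$expected$exclusion_reason)
  expect_equal(calls$best_hit_accession, fx$expected$best_hit_accession)
  expect_equal(calls$species, fx$expected$species)
  expect_equal(calls$host_groups, fx$expected$host_groups)
  # conflict between positive host metadata and negative literature is flagged
  expect_true(calls$conflict[calls$asv_id == "A13"])
  expect_false(any(calls$conflict[calls$asv_id != "A13"]))
})

test_that("conflict policy can let literature evidence win", {
  fx <- classifier_fixture()
  calls <- classify_asvs(fx$hits, fx$records, fx$literature,
                         asv_ids = "A13", conflict_policy = "literature")
  expect_equal(calls$status, "non_parasite")
  expect_equal(calls$provenance, "none")
})

test_that("calls partition ASVs and satisfy the provenance identities", {
  fx <- classifier_fixture()
  calls <- classify_asvs(fx$hits, fx$records, fx$literature,
                         asv_ids = fx$asv_ids, taxonomy = fx$taxonomy)
  expect_equal(nrow(calls), length(fx$asv_ids))
  expect_equal(anyDuplicated(calls$asv_id), 0L)
  acc <- call_accounting(calls)
  expect_true(acc$consistent)
  expect_equal(acc$parasites + acc$non_parasites, acc$total)
  expect_equal(sum(acc$by_provenance), acc$parasites)
  # parasite status iff positive provenance; exclusion reason only for negatives
  expect_true(all((calls$status == "parasite") ==
                    (calls$provenance %in% c("both", "literature_only",
                                             "genbank_only"))))
  expect_true(all(calls$exclusion_reason[calls$status == "parasite"] == "none"))
  expect_true(all(calls$provenance[calls$status == "non_parasite"] == "none"))
})

test_that("classification is invariant to input row order", {
  fx <- classifier_fixture()
  ref <- classify_asvs(fx$hits, fx$records, fx$literature,
                       asv_ids = fx$asv_ids, taxonomy = fx$taxonomy)
  set.seed(3)
  for (rep in 1:5) {
    shuf <- classify_asvs(fx$hits[sample(nrow(fx$hits)), ],
                          fx$records[sample(nrow(fx$records)), ],
                          fx$literature[sample(nrow(fx$literature)), ],
                          asv_ids = fx$asv_ids, taxonomy = fx$taxonomy)
    expect_equal(shuf, ref)
  }
})

test_that("adding positive literature evidence is monotone", {
  fx <- classifier_fixture()
  before <- classify_asvs(fx$hits, fx$records, literature = NULL,
                          asv_ids = fx$asv_ids, taxonomy = fx$taxonomy)
  after <- classify_asvs(fx$hits, fx$records,
                         literature = fx$literature[fx$literature$is_parasite, ],
                         asv_ids = fx$asv_ids, taxonomy = fx$taxonomy)
  rank <- c(none = 0, genbank_only = 1, literature_only = 1, both = 2)
  expect_true(all(rank[after$provenance] >= rank[before$provenance]))
  # no parasite became non-parasite
  expect_true(all(!(before$status == "parasite" & after$status == "non_parasite")))
})

test_that("host groups fall back to unresolved and union over sources", {
  calls <- data.frame(asv_id = c("X1", "X2"), status = "parasite",
                      host_strings = c("Homo sapiens|Zea mays", ""),
                      stringsAsFactors = FALSE)
  out <- assign_host_groups(calls)
  expect_equal(out$host_groups[1], "humans|terrestrial_plants")
  expect_equal(out$host_groups[2], "unresolved")
  np <- data.frame(asv_id = "X3", status = "non_parasite",
                   host_strings = "", stringsAsFactors = FALSE)
  expect_warning(assign_host_groups(np), "no parasite calls")
})
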