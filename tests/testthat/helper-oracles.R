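# Independent oracles and hand-built fixtures shared across tests.

# Poisson log-link deviance, computed from first principles
poisson_dev_oracle <- function(y, mu) {
  2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
}

# Independent IRLS fit of a Poisson log-link GLM (no stats::glm internals)
irls_poisson <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- numeric(ncol(X))
  beta[1] <- log(mean(y) + 0.01)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    XtW <- t(X * mu)
    beta_new <- drop(solve(XtW %*% X, XtW %*% z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  mu <- exp(drop(X %*% beta))
  list(coef = beta, deviance = poisson_dev_oracle(y, mu))
}

make_hit <- function(q, s, pident, bitscore, evalue = 1e-50, qcovs = 100) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = 250L,
             mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 250L,
             sstart = 1L, send = 250L, evalue = evalue, bitscore = bitscore,
             qcovs = qcovs, stringsAsFactors = FALSE)
}

make_record <- function(accession, species = NA_character_, hosts = "",
                        source_note = "", lineage = "Eukaryota;Fungi;Chytridiomycota",
                        sequence = "ACGT") {
  data.frame(accession = accession, lineage = lineage, species = species,
             marker = "18S", hosts = hosts, source_note = source_note,
             sequence = sequence, stringsAsFactors = FALSE)
}

# Hand-built fixture exercising every classifier rule branch; the expected
# call table was derived by hand from the documented rules.
classifier_fixture <- function() {
  hits <- rbind(
    make_hit("A01", "REF01", 95.0, 480),
    make_hit("A02", "REF02", 99.0, 490),
    make_hit("A03", "REF03", 98.6, 470),
    make_hit("A05", "REF05", 94.0, 460),
    make_hit("A06", "REF06", 93.0, 450),
    make_hit("A07", "REF07", 96.0, 440),
    make_hit("A08", "REF08", 97.0, 430),
    make_hit("A10", "REF10", 89.9, 480),            # below identity
    make_hit("A11", "REF11", 97.0, 480, qcovs = 99), # below cover
    make_hit("A12", "REF12", 92.0, 420),
    make_hit("A13", "REF13", 99.2, 410),
    make_hit("A14", "REF14", 98.0, 400),            # boundary identity
    make_hit("A15", "REF15A", 95.0, 500, evalue = 1e-70),
    make_hit("A15", "REF15B", 96.0, 500, evalue = 1e-65),
    make_hit("A15", "REF15C", 99.0, 490, evalue = 1e-80),
    make_hit("A16", "MISSING", 95.0, 480),
    make_hit("A17", "REF17", 95.0, 480),
    make_hit("A18", "REF18", 95.0, 480)
  )
  records <- rbind(
    make_record("REF01", hosts = "Daphnia galeata"),
    make_record("REF02", species = "Zygorhizidium planktonicum",
                hosts = "Asterionella formosa"),
    make_record("REF03", species = "Aphelidium desmodesmi", hosts = ""),
    make_record("REF05", hosts = "lake water"),
    make_record("REF06", hosts = "decaying log"),
    make_record("REF07", hosts = "algal endosymbiont of Paramecium bursaria"),
    make_record("REF08", hosts = "Desmodesmus armatus",
                source_note = "pathobiome of diseased host"),
    make_record("REF10", hosts = "Daphnia galeata"),
    make_record("REF11", hosts = "Daphnia galeata"),
    make_record("REF12", hosts = "Daphnia galeata|lake water"),
    make_record("REF13", species = "Ustilago esculenta", hosts = "Homo sapiens"),
    make_record("REF14", species = "Pythium insidiosum", hosts = "Zea mays"),
    make_record("REF15A", hosts = "Triturus cristatus"),
    make_record("REF15B", hosts = "lake water"),
    make_record("REF15C", hosts = "soil"),
    make_record("REF17", hosts = ""),
    make_record("REF18", hosts = "unknown flagellate isolate XYZ")
  )
  literature <- data.frame(
    species_name = c("Zygorhizidium planktonicum", "Aphelidium desmodesmi",
                     "Nematopsis temporariae", "Ustilago esculenta",
                     "Pythium insidiosum"),
    is_parasite = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    hosts = c("Asterionella formosa", "Desmodesmus armatus",
              "Salamandra salamandra", "", ""),
    source = "hand-fixture", stringsAsFactors = FALSE)
  taxonomy <- data.frame(
    asv_id = c("A04"), dataset = "protist",
    lineage = "Eukaryota;Alveolata;Apicomplexa",
    species = "Nematopsis temporariae", stringsAsFactors = FALSE)
  asv_ids <- sprintf("A%02d", 1:18)
  expected <- data.frame(
    asv_id = asv_ids,
    status = c("parasite", "parasite", "parasite", "parasite",
               "non_parasite", "non_parasite", "non_parasite", "non_parasite",
               "non_parasite", "non_parasite", "non_parasite", "parasite",
               "parasite", "parasite", "parasite", "non_parasite",
               "non_parasite", "parasite"),
    provenance = c("genbank_only", "both", "literature_only", "literature_only",
                   "none", "none", "none", "none",
                   "none", "none", "none", "genbank_only",
                   "genbank_only", "genbank_only", "genbank_only", "none",
                   "none", "genbank_only"),
    exclusion_reason = c("none", "none", "none", "none",
                         "abiotic_substrate", "nonliving_substrate",
                         "symbiont", "symbiont",
                         "no_host_evidence", "no_host_evidence",
                         "no_host_evidence", "none",
                         "none", "none", "none", "no_host_evidence",
                         "no_host_evidence", "none"),
    best_hit_accession = c("REF01", "REF02", "REF03", NA,
                           "REF05", "REF06", "REF07", "REF08",
                           NA, NA, NA, "REF12",
                           "REF13", "REF14", "REF15A", "MISSING",
                           "REF17", "REF18"),
    species = c(NA, "Zygorhizidium planktonicum", "Aphelidium desmodesmi",
                "Nematopsis temporariae", NA, NA, NA, NA, NA, NA, NA, NA,
                "Ustilago esculenta", NA, NA, NA, NA, NA),
    host_groups = c("crustaceans", "diatoms", "green_algae", "salamanders",
                    NA, NA, NA, NA, NA, NA, NA, "crustaceans",
                    "humans", "terrestrial_plants", "salamanders", NA, NA,
                    "unresolved"),
    stringsAsFactors = FALSE)
  list(hits = hits, records = records, literature = literature,
       taxonomy = taxonomy, asv_ids = asv_ids, expected = expected)
}

# tiny decontamination fixture: 2 runs, 4 samples, 1 control per run
tiny_decontam <- function() {
  counts <- rbind(
    S1 = c(A = 10L, B = 5L, C = 0L),
    S2 = c(A = 3L, B = 0L, C = 7L),
    N1 = c(A = 0L, B = 2L, C = 0L),
    S3 = c(A = 4L, B = 6L, C = 1L),
    N2 = c(A = 0L, B = 0L, C = 0L))
  metadata <- data.frame(
    sample_id = c("S1", "S2", "N1", "S3", "N2"),
    run = c("run1", "run1", "run1", "run2", "run2"),
    is_negative_control = c(FALSE, FALSE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  list(counts = counts, metadata = metadata)
}
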