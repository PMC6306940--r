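# Shared fixtures.  Small hand-built worlds are rebuilt per call; the
# full-scale simulated dataset (50,000 cases, the generator's stated
# defaults at seed 1) is computed lazily once per test run and reused by
# the acceptance tests.

.fixture_cache <- new.env(parent = emptyenv())

# 4-level toy tree mirroring sibling specific terms under one disease
# class: 1 root, 2 level-2 classes, 4 level-3 groups, 8 level-4 leaves,
# plus an indication branch
toy_hierarchy <- function() {
  phenotype_hierarchy(data.frame(
    term_id = c("SOC1", "CARD", "GAST",
                "CAD", "ARR", "NAUS", "ULC",
                "cad_dis", "cad_thromb", "arr_fib", "arr_tach",
                "naus_vom", "naus_mot", "ulc_gas", "ulc_duo",
                "ISOC", "INEO", "ISKIN", "ISKINMAL"),
    name = c("disorders", "cardiac disorders", "gastric disorders",
             "coronary artery conditions", "arrhythmias", "nausea",
             "ulcers",
             "coronary artery disease", "coronary artery thrombosis",
             "atrial fibrillation", "tachycardia",
             "vomiting", "motion sickness", "gastric ulcer",
             "duodenal ulcer",
             "indications", "neoplasms", "skin neoplasms",
             "skin neoplasm malignant"),
    level = c(1, 2, 2, 3, 3, 3, 3, 4, 4, 4, 4, 4, 4, 4, 4, 1, 2, 3, 4),
    parent_id = c(NA, "SOC1", "SOC1", "CARD", "CARD", "GAST", "GAST",
                  "CAD", "CAD", "ARR", "ARR", "NAUS", "NAUS", "ULC",
                  "ULC", NA, "ISOC", "INEO", "ISKIN")))
}

toy_dictionary <- function() {
  drug_dictionary(data.frame(
    drug_id = c("D1", "D1", "D2", "D3", "D3", "D4"),
    canonical_name = c("aspirin", "aspirin", "metoprolol", "tylenol",
                       "tylenol", "vemurafenib"),
    synonym = c("aspirin", "acetylsalicylic acid", "metoprolol", "tylenol",
                "acetaminophen", "vemurafenib"),
    atc_codes = c("N02BA01", "N02BA01", "C07AB02", "N02BE01", "N02BE01",
                  "L01XE15")))
}

toy_links <- function() {
  target_links(data.frame(
    drug_id = c("D1", "D1", "D2", "D3", "D4", "D1", "D3"),
    protein_id = c("PTGS1", "PTGS2", "ADRB1", "PTGS2", "BRAF",
                   "CYP2C9", "CYP1A2"),
    role = c("target", "target", "target", "target", "target",
             "enzyme", "enzyme"),
    action = c("antagonist", "antagonist", "antagonist", "antagonist",
               "antagonist", "unknown", "unknown")))
}

toy_annotations <- function() {
  protein_annotations(data.frame(
    protein_id = c("PTGS1", "PTGS2", "ADRB1", "BRAF", "CYP2C9", "CYP1A2"),
    gene_symbol = c("PTGS1", "PTGS2", "ADRB1", "BRAF", "CYP2C9", "CYP1A2"),
    pathway_ids = c("PW_PG", "PW_PG", "PW_ADR", "PW_MAPK", "", "")))
}

# small hand corpus over the toy world; exercised by integration and
# signal unit tests where counts are enumerable by hand
toy_corpus <- function() {
  ae_corpus(
    case_id = sprintf("T%02d", 1:6),
    report_date = as.Date(c("2001-03-01", "2005-06-15", "2010-01-01",
                            "2012-08-20", NA, "2016-12-01")),
    drug_mentions = list("aspirin", c("Aspirin", "metoprolol"), "TYLENOL",
                         "vemurafenib", c("metoprolol", "UNKNOWN"),
                         "acetaminophen"),
    indications = list("ISKINMAL", "ISKINMAL", "INEO", "ISKINMAL",
                       character(0), "INEO"),
    reactions = list(c("cad_dis", "naus_vom"), "cad_thromb", "naus_vom",
                     "arr_fib", "cad_dis", character(0)),
    outcomes = list("DE", c("HO", "DE"), "OT", character(0), "DE", "OT"))
}

toy_mapped <- function() {
  map_corpus(toy_corpus(), toy_dictionary())
}

toy_annotated <- function() {
  annotate_cases(toy_mapped(), toy_links(), toy_annotations(),
                 toy_dictionary())
}

# the generator's stated default world at seed 1, shared across tests
big_sim <- function() {
  if (is.null(.fixture_cache$big)) {
    cfg <- generator_config(seed = 1)
    .fixture_cache$big <- simulate_dataset(cfg)
  }
  .fixture_cache$big
}

big_mapped <- function() {
  if (is.null(.fixture_cache$big_mapped)) {
    ds <- big_sim()
    .fixture_cache$big_mapped <- map_corpus(ds$corpus, ds$world$dictionary,
                                            ds$world$blacklist)
  }
  .fixture_cache$big_mapped
}

big_annotated <- function() {
  if (is.null(.fixture_cache$big_annotated)) {
    ds <- big_sim()
    .fixture_cache$big_annotated <-
      annotate_cases(big_mapped(), ds$world$links, ds$world$annotations,
                     ds$world$dictionary)
  }
  .fixture_cache$big_annotated
}
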