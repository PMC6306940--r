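test_that("normalize_string canonicalizes and is idempotent", {
  expect_equal(normalize_string("  Aspirin®  "), "aspirin")
  expect_equal(normalize_string("TYLENOL-500mg  (tablet)"),
               "tylenol 500mg tablet")
  expect_equal(normalize_string("aspirin"), "aspirin")
  set.seed(42)
  rand <- vapply(1:200, function(i)
    rawToChar(as.raw(sample(32:126, sample(1:25, 1), TRUE))), character(1))
  expect_equal(normalize_string(normalize_string(rand)),
               normalize_string(rand))
})

test_that("map_name walks the stepwise procedure", {
  dict <- toy_dictionary()
  # blacklist consulted before anything else
  for (term in c("UNKNOWN", "unk", " Unknown ")) {
    r <- map_name(term, dict)
    expect_equal(r$stage, "blacklist")
    expect_length(r$matches, 0)
  }
  # exact synonym
  r <- map_name("Acetylsalicylic Acid", dict)
  expect_equal(r$stage, "exact")
  expect_equal(r$matches, "D1")
  expect_equal(r$distance, 0L)
  # token-part phase on a dose-form phrase
  r <- map_name("TYLENOL 500MG TABLET", dict)
  expect_equal(r$stage, "part")
  expect_equal(r$matches, "D3")
  # multi-drug phrases split on +, / and "and"
  for (phrase in c("aspirin + metoprolol", "aspirin/metoprolol",
                   "Aspirin and Metoprolol")) {
    r <- map_name(phrase, dict)
    expect_setequal(r$matches, c("D1", "D2"))
  }
  # more than 5 edits from every synonym, no substring: unmapped
  r <- map_name("zzqqxxyyww", dict)
  expect_equal(r$stage, "unmapped")
  expect_length(r$matches, 0)
})

test_that("fuzzy matching agrees with a brute-force Levenshtein oracle", {
  dict <- toy_dictionary()
  cases <- c("aspjrin",        # 1 substitution
             "metoprollol",    # 1 insertion
             "vemurafnib",     # 1 deletion
             "asqirim",        # 2 substitutions
             "acetaminophen1965")
  for (verb in cases) {
    r <- map_name(verb, dict)
    norm <- normalize_string(verb)
    d <- vapply(dict$synonyms$syn_norm, lev_oracle, numeric(1), s = norm)
    dmin <- min(d)
    if (dmin <= 5) {
      expect_equal(r$stage, "fuzzy", info = verb)
      expect_equal(r$distance, as.integer(dmin), info = verb)
      expect_setequal(r$matches,
                      unique(dict$synonyms$drug_id[d == dmin]))
    } else {
      expect_equal(r$stage, "unmapped", info = verb)
    }
  }
})

test_that("ties at minimal distance return all drugs, marked ambiguous", {
  dict <- drug_dictionary(data.frame(
    drug_id = c("DA", "DB"), canonical_name = c("brixal", "brixol"),
    synonym = c("brixal", "brixol"), atc_codes = c("", "")))
  r <- map_name("brixul", dict)
  expect_true(r$ambiguous)
  expect_setequal(r$matches, c("DA", "DB"))
  expect_equal(r$distance, 1L)
})

test_that("no fuzzy match ever exceeds 5 edits", {
  ds <- simulate_dataset(generator_config(seed = 13, n_cases = 1500,
                                          n_drugs = 20, n_proteins = 25,
                                          typo_prob = 0.5, max_edits = 3))
  mapped <- map_corpus(ds$corpus, ds$world$dictionary, ds$world$blacklist)
  fuzzy <- mapped$mentions[stage == "fuzzy"]
  expect_gt(nrow(fuzzy), 0)
  expect_true(all(fuzzy$distance >= 1 & fuzzy$distance <= 5))
})

test_that("mapping is a pure function of the string (corpus order invariant)", {
  ds <- simulate_dataset(generator_config(seed = 17, n_cases = 400,
                                          n_drugs = 12, n_proteins = 15))
  m1 <- map_corpus(ds$corpus, ds$world$dictionary, ds$world$blacklist)
  shuffled <- ds$corpus[sample(nrow(ds$corpus))]
  data.table::setattr(shuffled, "class", class(ds$corpus))
  m2 <- map_corpus(shuffled, ds$world$dictionary, ds$world$blacklist)
  k1 <- m1$mentions[order(verbatim)]
  k2 <- m2$mentions[order(verbatim)]
  expect_equal(k1$stage, k2$stage)
  expect_equal(k1$matches, k2$matches)
  # and matches each map_name result recomputed in isolation
  for (i in sample(nrow(k1), 25)) {
    solo <- map_name(k1$verbatim[i], ds$world$dictionary,
                     ds$world$blacklist)
    expect_equal(solo$stage, k1$stage[i])
    expect_setequal(solo$matches, k1$matches[[i]])
  }
})

test_that("coverage statistics behave at the extremes", {
  dict <- toy_dictionary()
  clean <- ae_corpus(case_id = c("A", "B"),
                     drug_mentions = list("aspirin", c("tylenol", "UNK")))
  m <- map_corpus(clean, dict)
  expect_equal(m$coverage$frac_names_mapped, 1.0)
  expect_equal(m$coverage$frac_reports_mapped, 1.0)

  allblack <- ae_corpus(case_id = c("A", "B"),
                        drug_mentions = list("UNKNOWN", "UNK"))
  m2 <- map_corpus(allblack, dict)
  expect_equal(m2$coverage$frac_reports_mapped, 0.0)
})

test_that("corrupted mentions overwhelmingly map to the intended drug", {
  # scaled-down version of the full-scale acceptance property
  ds <- simulate_dataset(generator_config(seed = 23, n_cases = 2000,
                                          n_drugs = 25, n_proteins = 30,
                                          typo_prob = 0.4, max_edits = 2))
  mapped <- map_corpus(ds$corpus, ds$world$dictionary, ds$world$blacklist)
  mm <- ds$truth$mention_map[!is.na(drug_id)]
  hit <- mapped$mentions$matches[match(mm$verbatim, mapped$mentions$verbatim)]
  ok <- mapply(function(d, m) d %in% m, mm$drug_id, hit)
  expect_gte(mean(ok), 0.95)
})
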