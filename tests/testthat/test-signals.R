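test_that("build_contingency matches hand enumeration on the toy corpus", {
  ann <- toy_annotated()
  h <- toy_hierarchy()
  # PTGS2 (aspirin, tylenol) against the level-3 nausea group:
  # exposed cases: T01 (aspirin), T02 (aspirin), T03 (tylenol), T06
  # (acetaminophen); nausea events roll up from naus_vom: T01, T03
  tab <- build_contingency(ann, "target", "PTGS2", "reaction", "NAUS", 3, h)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(2, 2, 0, 2))
  expect_equal(tab$N, nrow(ann))
  # entity present in no case
  tab0 <- build_contingency(ann, "target", "GHOST", "reaction", "NAUS", 3, h)
  expect_equal(c(tab0$a, tab0$b), c(0, 0))
  # unknown event term errors; wrong level errors
  expect_error(build_contingency(ann, "target", "PTGS2", "reaction",
                                 "NOPE", 3, h), "unknown event")
  expect_error(build_contingency(ann, "target", "PTGS2", "reaction",
                                 "NAUS", 2, h), "level")
  # outcome events need no hierarchy
  tabo <- build_contingency(ann, "target", "ADRB1", "outcome", "DE")
  expect_equal(c(tabo$a, tabo$b, tabo$c, tabo$d), c(2, 0, 1, 3))
})

test_that("cells always partition the corpus", {
  ds <- simulate_dataset(generator_config(seed = 29, n_cases = 250,
                                          n_drugs = 12, n_proteins = 15))
  mapped <- map_corpus(ds$corpus, ds$world$dictionary, ds$world$blacklist)
  ann <- annotate_cases(mapped, ds$world$links, ds$world$annotations,
                        ds$world$dictionary)
  targets <- unique(unlist(ann$target_ids))
  leaves <- ds$world$hierarchy$terms[level == 4][1:5, term_id]
  for (tg in head(targets, 4)) for (ev in leaves) {
    tab <- build_contingency(ann, "target", tg, "reaction", ev, 4,
                             ds$world$hierarchy)
    expect_equal(tab$a + tab$b + tab$c + tab$d, nrow(ann))
  }
})

test_that("prr implements a(c+d)/(c(a+b)) with exact degenerate handling", {
  # the published beta-blocker table: ratio of 241/1308 vs 4059/17177
  tab <- contingency_table(241, 1067, 4059, 13118)
  oracle <- (241 / 1308) / (4059 / 17177)
  expect_equal(prr(tab), oracle, tolerance = 1e-12)
  expect_equal(round(prr(tab), 4), 0.7797)
  # equal proportions give exactly 1
  expect_equal(prr(contingency_table(10, 90, 20, 180)), 1.0)
  # a = 0 with c > 0 gives 0
  expect_equal(prr(contingency_table(0, 50, 10, 100)), 0)
  # degenerate tables raise unless permissive
  expect_error(prr(contingency_table(5, 5, 0, 10)), "c = 0")
  expect_error(prr(contingency_table(0, 0, 5, 10)), "a\\+b = 0")
  expect_equal(prr(contingency_table(5, 5, 0, 10), permissive = TRUE), Inf)
  expect_true(is.nan(prr(contingency_table(0, 0, 5, 10),
                         permissive = TRUE)))
})

test_that("fisher_exact reproduces the published example and the oracle", {
  tab <- contingency_table(241, 1067, 4059, 13118)
  # printed as 0.000012 (two significant figures)
  expect_equal(signif(fisher_exact(tab), 2), 1.2e-5)
  # symmetric table
  expect_equal(fisher_exact(contingency_table(7, 13, 7, 13)), 1.0)
  # enumeration oracle on random small tables, both sidednesses
  set.seed(57)
  for (i in 1:200) {
    cl <- random_table(40)
    tab <- contingency_table(cl[1], cl[2], cl[3], cl[4])
    expect_equal(fisher_exact(tab, "two"),
                 fisher_enum_oracle(cl[1], cl[2], cl[3], cl[4], "two"),
                 tolerance = 1e-12)
    expect_equal(fisher_exact(tab, "one"),
                 fisher_enum_oracle(cl[1], cl[2], cl[3], cl[4], "one"),
                 tolerance = 1e-12)
  }
})

test_that("qvalues implements BH step-up exactly", {
  expect_equal(qvalues(0.037), 0.037)
  expect_equal(qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(qvalues(rep(0.2, 6)), rep(0.2, 6))
  expect_error(qvalues(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(91)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    q <- qvalues(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-14)
    # monotone: sorting by p sorts by q
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  # Storey variant is never larger than BH
  p <- runif(500)
  expect_true(all(qvalues(p, "storey") <= qvalues(p) + 1e-15))
})

test_that("profile_entity ranks the planted reaction first", {
  ds <- simulate_dataset(generator_config(seed = 37, n_cases = 12000,
                                          n_drugs = 20, n_proteins = 25,
                                          n_planted = 3,
                                          planted_multiplier = 8))
  mapped <- map_corpus(ds$corpus, ds$world$dictionary, ds$world$blacklist)
  ann <- annotate_cases(mapped, ds$world$links, ds$world$annotations,
                        ds$world$dictionary)
  filt <- signal_filter(min_entity_support = 100)
  pl <- ds$world$planted
  for (j in seq_len(nrow(pl))) {
    prof <- profile_entity(ann, "target", pl$protein_id[j], "reaction", 4,
                           ds$world$hierarchy, filt)
    expect_equal(prof$event_id[1], pl$term_id[j])
    expect_true(prof$flagged[1])
  }
  # profile PRRs match per-pair recomputation
  prof <- profile_entity(ann, "target", pl$protein_id[1], "reaction", 4,
                         ds$world$hierarchy, filt)
  for (i in sample(nrow(prof), 10)) {
    tab <- build_contingency(ann, "target", pl$protein_id[1], "reaction",
                             prof$event_id[i], 4, ds$world$hierarchy)
    expect_equal(prof$prr[i], prr(tab, permissive = TRUE))
    expect_equal(prof$p[i], fisher_exact(tab))
  }
  # support gate errors, naming the threshold
  expect_error(profile_entity(ann, "target", pl$protein_id[1], "reaction",
                              4, ds$world$hierarchy,
                              signal_filter(min_entity_support = 1e6)),
               "below min_entity_support")
})

test_that("screen_all agrees with profile_entity modulo q scope", {
  ann <- toy_annotated()
  h <- toy_hierarchy()
  filt <- signal_filter(min_entity_support = 1, min_cooccurrence = 1)
  scr <- screen_all(ann, "target", "reaction", 3, h, filt)
  expect_equal(sum(scr$a + scr$b + scr$c + scr$d != nrow(ann)), 0)
  prof <- profile_entity(ann, "target", "PTGS2", "reaction", 3, h, filt)
  sub <- scr[entity_id == "PTGS2"][match(prof$event_id, event_id)]
  expect_equal(sub$a, prof$a)
  expect_equal(sub$prr, prof$prr)
  expect_equal(sub$p, prof$p)
  # empty corpus gives an empty table
  empty <- ann[0]
  data.table::setattr(empty, "class", class(ann))
  scr0 <- screen_all(empty, "target", "reaction", 3, h, filt)
  expect_equal(nrow(scr0), 0L)
})

test_that("mechanism profiles separate agonist- and antagonist-driven effects", {
  # constructed world: target TGT hit by agonist drug AGO and antagonist
  # drug ANT; only antagonist exposure confers the reaction
  n <- 900
  set.seed(71)
  drug <- sample(c("ago", "ant", "none"), n, TRUE)
  react <- ifelse(drug == "ant", runif(n) < 0.25, runif(n) < 0.02)
  corpus <- ae_corpus(
    case_id = sprintf("M%04d", 1:n),
    report_date = as.Date("2010-01-01"),
    drug_mentions = lapply(drug, function(d)
      if (d == "none") "tylenol" else d),
    indications = rep(list(character(0)), n),
    reactions = lapply(react, function(r) if (r) "cad_dis" else character(0)),
    outcomes = rep(list(character(0)), n))
  dict <- drug_dictionary(data.frame(
    drug_id = c("DAGO", "DANT", "D3"),
    canonical_name = c("ago", "ant", "tylenol"),
    synonym = c("ago", "ant", "tylenol"), atc_codes = ""))
  links <- target_links(data.frame(
    drug_id = c("DAGO", "DANT", "D3"),
    protein_id = c("TGT", "TGT", "OTHER"),
    role = "target", action = c("agonist", "antagonist", "unknown")))
  ann <- annotate_cases(map_corpus(corpus, dict), links, NULL, dict)
  filt <- signal_filter(min_entity_support = 20, min_cooccurrence = 5)
  mp <- mechanism_profiles(ann, "TGT", "reaction", 4, toy_hierarchy(), filt)
  ant_row <- mp$antagonist[event_id == "cad_dis"]
  expect_true(ant_row$flagged)
  ago_row <- mp$agonist[event_id == "cad_dis"]
  expect_true(nrow(ago_row) == 0 || !ago_row$flagged)
  # each side's N equals its partition size
  n_ant <- sum(drug == "ant") + sum(drug == "none")
  expect_equal(ant_row$a + ant_row$b + ant_row$c + ant_row$d, n_ant)
})

test_that("a null screen keeps the significant fraction near the FDR target", {
  # scaled-down null world: all multipliers 1
  ds <- simulate_dataset(generator_config(seed = 43, n_cases = 10000,
                                          n_drugs = 40, n_proteins = 60,
                                          planted_multiplier = 1))
  mapped <- map_corpus(ds$corpus, ds$world$dictionary, ds$world$blacklist)
  ann <- annotate_cases(mapped, ds$world$links, ds$world$annotations,
                        ds$world$dictionary)
  scr <- screen_all(ann, "target", "reaction", 4, ds$world$hierarchy,
                    signal_filter(min_entity_support = 50,
                                  min_cooccurrence = 5))
  expect_gt(nrow(scr), 1000)
  expect_lte(mean(scr$significant), 0.07)
})
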