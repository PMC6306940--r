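test_that("case tables round trip losslessly in all three dialects", {
  set.seed(101)
  corpus <- toy_corpus()
  for (dialect in c("dollar", "tab", "comma")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_cases(corpus, path, dialect)
    back <- read_cases(path, dialect)
    expect_equal(back$case_id, corpus$case_id)
    expect_equal(back$report_date, corpus$report_date)
    for (col in c("drug_mentions", "indications", "reactions", "outcomes"))
      expect_equal(back[[col]], corpus[[col]], info = dialect)
  }
  # the same in-memory corpus written in two dialects reads back identical
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_cases(corpus, p1, "dollar")
  write_cases(corpus, p2, "tab")
  expect_equal(as.list(read_cases(p1, "dollar")),
               as.list(read_cases(p2, "tab")))
})

test_that("read_cases rejects rows without case_id and reports the count", {
  path <- withr::local_tempfile()
  writeLines(c("case_id\treport_date\tdrug_mentions\tindications\treactions\toutcomes",
               "C1\t2001-01-01\taspirin\t\tcad_dis\tDE",
               "\t2002-01-01\ttylenol\t\tnaus_vom\t",
               "C2\t\tmetoprolol\t\t\tOT"), path)
  expect_message(corpus <- read_cases(path, "tab"), "rejected 1 row")
  expect_equal(nrow(corpus), 2L)
  expect_equal(nrow(rejected_rows(corpus)), 1L)
  expect_true(is.na(corpus$report_date[2]))
})

test_that("duplicate case_id is an error naming the id", {
  path <- withr::local_tempfile()
  writeLines(c("case_id\treport_date\tdrug_mentions\tindications\treactions\toutcomes",
               "C7\t2001-01-01\taspirin\t\t\tDE",
               "C7\t2002-01-01\ttylenol\t\t\t"), path)
  expect_error(read_cases(path, "tab"), "C7")
})

test_that("hierarchy loads, is permutation invariant, and rejects bad trees", {
  h <- toy_hierarchy()
  expect_equal(nrow(h$terms), 19L)
  # every level-4 term has a level-2 ancestor
  leaves <- h$terms[level == 4, term_id]
  anc2 <- ancestor_at_level(h, leaves, 2)
  expect_false(anyNA(anc2))
  expect_true(all(h$terms[match(anc2, term_id), level] == 2L))

  # shuffled row order gives an identical hierarchy
  tab <- h$terms
  set.seed(7)
  h2 <- phenotype_hierarchy(tab[sample(nrow(tab))])
  expect_equal(data.table::setkey(data.table::copy(h2$ancestors), term_id),
               data.table::setkey(data.table::copy(h$ancestors), term_id))

  # parent at the same level
  bad <- data.frame(term_id = c("A", "B"), name = c("a", "b"),
                    level = c(2, 2), parent_id = c(NA, "A"))
  expect_error(phenotype_hierarchy(bad), "level")
  # orphan
  orphan <- data.frame(term_id = "X", name = "x", level = 2,
                       parent_id = "NOPE")
  expect_error(phenotype_hierarchy(orphan), "orphan|unknown parent")
})

test_that("ancestor_at_level returns the unique ancestor and is idempotent", {
  h <- toy_hierarchy()
  # sibling specific terms group under the same disease class
  expect_equal(ancestor_at_level(h, "cad_thromb", 2), "CARD")
  expect_equal(ancestor_at_level(h, "cad_dis", 2), "CARD")
  expect_equal(ancestor_at_level(h, "cad_thromb", 3),
               ancestor_at_level(h, "cad_dis", 3))
  # a term queried at its own level is itself
  expect_equal(ancestor_at_level(h, "CARD", 2), "CARD")
  # a root queried below its level errors
  expect_error(ancestor_at_level(h, "SOC1", 4), "above the requested level")
  # idempotence across every term and admissible level
  for (k in 1:4) {
    ok <- h$terms[level >= k, term_id]
    once <- ancestor_at_level(h, ok, k)
    expect_equal(ancestor_at_level(h, once, k), once)
  }
})

test_that("dictionary, link and annotation tables validate and round trip", {
  dict <- toy_dictionary()
  expect_equal(nrow(dict$concepts), 4L)
  p <- withr::local_tempfile()
  write_dictionary(dict, p)
  back <- read_dictionary(p)
  expect_equal(back$concepts[order(drug_id), .(drug_id, canonical_name)],
               dict$concepts[order(drug_id), .(drug_id, canonical_name)])
  expect_setequal(back$synonyms$synonym, dict$synonyms$synonym)

  # canonical name must be among the synonyms
  expect_error(drug_dictionary(data.frame(
    drug_id = "D9", canonical_name = "foo", synonym = "bar",
    atc_codes = "")), "canonical_name")

  links <- toy_links()
  p2 <- withr::local_tempfile()
  write_links(links, p2)
  expect_equal(as.data.frame(read_links(p2)), as.data.frame(links))
  expect_error(target_links(data.frame(
    drug_id = c("D1", "D1"), protein_id = c("P", "P"),
    role = c("target", "target"), action = c("agonist", "unknown"))),
    "duplicate")
  expect_error(target_links(data.frame(
    drug_id = "D1", protein_id = "P", role = "victim", action = "unknown")),
    "role")

  ann <- toy_annotations()
  p3 <- withr::local_tempfile()
  write_annotations(ann, p3)
  back <- read_annotations(p3)
  expect_equal(back$pathway_ids, ann$pathway_ids)
})

test_that("corpus invariants are enforced", {
  expect_error(ae_corpus(case_id = c("A", "A")), "duplicate")
  expect_error(ae_corpus(case_id = "A", outcomes = list("XX")),
               "outcome")
  expect_setequal(outcome_codes(),
                  c("DE", "LT", "HO", "DS", "CA", "RI", "OT"))
})
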