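#' @import data.table
#' @importFrom stats dhyper p.adjust qnorm rbinom runif setNames
#' @importFrom utils adist head tail
NULL

# -- shared constants ---------------------------------------------------------

.OUTCOME_CODES <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
.DIALECT_SEPS  <- c(dollar = "$", tab = "\t", comma = ",")
.CASE_COLS     <- c("case_id", "report_date", "drug_mentions",
                    "indications", "reactions", "outcomes")
.SET_COLS      <- c("drug_mentions", "indications", "reactions", "outcomes")

#' The seven clinical outcome codes
#'
#' Closed set of outcome codes a case report may carry, following the FAERS
#' convention: death (DE), life-threatening (LT), hospitalization (HO),
#' disability (DS), congenital anomaly (CA), required intervention (RI) and
#' other (OT).
#'
#' @return Character vector of the seven codes.
#' @export
#' @examples
#' outcome_codes()
outcome_codes <- function() .OUTCOME_CODES

.assert_cols <- function(dt, cols, what) {
  miss <- setdiff(cols, names(dt))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
}

.split_field <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

.join_field <- function(x) {
  vapply(x, function(v) paste(v, collapse = ";"), character(1))
}

# sorted unique union that never degrades to NULL
.sunion <- function(x) {
  if (is.null(x)) character(0) else sort(unique(x))
}

# -- case corpus --------------------------------------------------------------

#' Construct an adverse-event case corpus
#'
#' A corpus is a `data.table` with one row per de-identified case report and
#' list-columns for the multi-valued fields.  `drug_mentions` holds the
#' verbatim (unnormalized) strings exactly as reported; `indications` and
#' `reactions` hold phenotype term ids; `outcomes` is a subset of
#' [outcome_codes()].
#'
#' @param case_id Character vector of unique case identifiers.
#' @param report_date `Date` vector (NA allowed; dateless cases are retained
#'   but excluded by any temporal slice).
#' @param drug_mentions,indications,reactions,outcomes Lists of character
#'   vectors, one element per case.
#' @return An object of class `ae_corpus` (a `data.table`).
#' @export
ae_corpus <- function(case_id, report_date = as.Date(NA),
                      drug_mentions = list(), indications = list(),
                      reactions = list(), outcomes = list()) {
  n <- length(case_id)
  pad <- function(x) if (length(x) == 0L) rep(list(character(0)), n) else x
  dt <- data.table(
    case_id       = as.character(case_id),
    report_date   = as.Date(report_date),
    drug_mentions = pad(drug_mentions),
    indications   = pad(indications),
    reactions     = pad(reactions),
    outcomes      = pad(outcomes)
  )
  validate_corpus(dt)
}

#' @rdname ae_corpus
#' @param dt A `data.table` with the corpus columns, to validate and bless.
#' @export
validate_corpus <- function(dt) {
  .assert_cols(dt, .CASE_COLS, "case corpus")
  if (anyNA(dt$case_id) || any(!nzchar(dt$case_id)))
    stop("corpus contains rows with missing case_id", call. = FALSE)
  dup <- dt$case_id[duplicated(dt$case_id)]
  if (length(dup))
    stop(sprintf("duplicate case_id: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  bad_out <- setdiff(unique(unlist(dt$outcomes)), .OUTCOME_CODES)
  if (length(bad_out))
    stop(sprintf("unknown outcome code(s): %s",
                 paste(bad_out, collapse = ", ")), call. = FALSE)
  setattr(dt, "class", unique(c("ae_corpus", class(dt))))
  dt[]
}

#' @export
print.ae_corpus <- function(x, ...) {
  cat(sprintf("<ae_corpus> %d case reports (%d dated)\n",
              nrow(x), sum(!is.na(x$report_date))))
  NextMethod()
}

#' Read a case-report table
#'
#' Reads a flattened one-case-per-row delimited table.  Three dialects are
#' accepted: `"dollar"` ("$"-separated, the FAERS quarterly-file convention),
#' `"tab"` and `"comma"`.  Multi-valued fields use ";" as the intra-field
#' separator.  Rows with a missing `case_id` are not silently dropped: they
#' are collected into a rejects table available via [rejected_rows()], and
#' their count is reported with a message.  A duplicate `case_id` is an
#' error naming the offending id.
#'
#' @param path Path to the delimited file (UTF-8, header row required).
#' @param dialect One of `"dollar"`, `"tab"`, `"comma"`.
#' @return An `ae_corpus`; rejected rows (if any) in `attr(, "rejects")`.
#' @seealso [write_cases()]
#' @export
read_cases <- function(path, dialect = c("dollar", "tab", "comma")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- fread(path, sep = .DIALECT_SEPS[[dialect]], quote = "\"",
               colClasses = "character", header = TRUE,
               na.strings = NULL, encoding = "UTF-8")
  .assert_cols(raw, .CASE_COLS, sprintf("case table '%s'", path))
  bad <- !nzchar(raw$case_id)
  rejects <- NULL
  if (any(bad)) {
    rejects <- copy(raw[bad])
    rejects[, reject_reason := "missing case_id"]
    message(sprintf("read_cases: rejected %d row(s) with missing case_id",
                    sum(bad)))
    raw <- raw[!bad]
  }
  corpus <- ae_corpus(
    case_id       = raw$case_id,
    report_date   = suppressWarnings(as.Date(
      ifelse(nzchar(raw$report_date), raw$report_date, NA_character_))),
    drug_mentions = .split_field(raw$drug_mentions),
    indications   = .split_field(raw$indications),
    reactions     = .split_field(raw$reactions),
    outcomes      = .split_field(raw$outcomes)
  )
  setattr(corpus, "rejects", rejects)
  corpus
}

#' Rejected rows of the last read
#'
#' @param corpus A corpus returned by [read_cases()].
#' @return A `data.table` of rejected raw rows with a `reject_reason`
#'   column, or `NULL` when every row parsed.
#' @export
rejected_rows <- function(corpus) attr(corpus, "rejects", exact = TRUE)

#' Write a case-report table
#'
#' Inverse of [read_cases()]; round trips are lossless for all three
#' dialects.  Fields containing the record separator are quoted in the comma
#' dialect and rejected in the dollar/tab dialects (FAERS-style files do not
#' quote).
#'
#' @param corpus An `ae_corpus`.
#' @param path Output path.
#' @param dialect One of `"dollar"`, `"tab"`, `"comma"`.
#' @export
write_cases <- function(corpus, path, dialect = c("dollar", "tab", "comma")) {
  dialect <- match.arg(dialect)
  sep <- .DIALECT_SEPS[[dialect]]
  flat <- data.table(
    case_id       = corpus$case_id,
    report_date   = ifelse(is.na(corpus$report_date), "",
                           format(corpus$report_date, "%Y-%m-%d")),
    drug_mentions = .join_field(corpus$drug_mentions),
    indications   = .join_field(corpus$indications),
    reactions     = .join_field(corpus$reactions),
    outcomes      = .join_field(corpus$outcomes)
  )
  has_sep <- vapply(flat, function(col) any(grepl(sep, col, fixed = TRUE)),
                    logical(1))
  if (any(has_sep) && dialect != "comma")
    stop(sprintf("field value contains the '%s' record separator; use the comma dialect",
                 sep), call. = FALSE)
  fwrite(flat, path, sep = sep, quote = dialect == "comma", col.names = TRUE)
  invisible(path)
}

# -- phenotype hierarchy ------------------------------------------------------

#' Construct a 4-level phenotype hierarchy
#'
#' Terms form a forest of 4-level trees: level 1 is the broadest class
#' (system-organ-class-like) and level 4 the most specific
#' (preferred-term-like).  Every non-root term names a parent exactly one
#' level above it, so each term has exactly one ancestor per level at or
#' above its own.
#'
#' @param terms A `data.frame`/`data.table` with columns `term_id`, `name`,
#'   `level` (integer 1-4) and `parent_id` (NA/empty iff level 1).
#' @return An object of class `phenotype_hierarchy` containing the term
#'   table and a precomputed term-by-level ancestor lookup.
#' @export
phenotype_hierarchy <- function(terms) {
  terms <- as.data.table(terms)
  .assert_cols(terms, c("term_id", "name", "level", "parent_id"), "hierarchy")
  terms <- terms[, .(term_id = as.character(term_id), name = as.character(name),
                     level = as.integer(level),
                     parent_id = {
                       p <- as.character(parent_id)
                       fifelse(is.na(p) | !nzchar(p), NA_character_, p)
                     })]
  if (anyDuplicated(terms$term_id))
    stop("duplicate term_id in hierarchy", call. = FALSE)
  if (any(is.na(terms$level)) || any(terms$level < 1L | terms$level > 4L))
    stop("term level must be an integer in 1..4", call. = FALSE)
  root_ok <- xor(terms$level == 1L, !is.na(terms$parent_id))
  if (!all(root_ok))
    stop(sprintf("parent_id must be absent iff level == 1 (offending: %s)",
                 paste(head(terms$term_id[!root_ok], 5), collapse = ", ")),
         call. = FALSE)
  nonroot <- terms[!is.na(parent_id)]
  lvl <- setNames(terms$level, terms$term_id)
  orphan <- !(nonroot$parent_id %in% terms$term_id)
  if (any(orphan))
    stop(sprintf("orphan term(s) with unknown parent: %s",
                 paste(head(nonroot$term_id[orphan], 5), collapse = ", ")),
         call. = FALSE)
  bad_lvl <- lvl[nonroot$parent_id] != nonroot$level - 1L
  if (any(bad_lvl))
    stop(sprintf("parent level must equal level - 1 (offending: %s)",
                 paste(head(nonroot$term_id[bad_lvl], 5), collapse = ", ")),
         call. = FALSE)
  # strict level decrease toward the root makes cycles impossible; build the
  # per-level ancestor lookup by walking parents three times at most
  anc <- terms[, .(term_id, level, anc1 = NA_character_, anc2 = NA_character_,
                   anc3 = NA_character_, anc4 = NA_character_)]
  par <- setNames(terms$parent_id, terms$term_id)
  for (k in 1:4) {
    col <- paste0("anc", k)
    cur <- ifelse(terms$level >= k, terms$term_id, NA_character_)
    steps <- terms$level - k
    steps[steps < 0L] <- 0L
    for (s in seq_len(max(steps, 0L))) {
      move <- !is.na(cur) & steps >= s
      cur[move] <- par[cur[move]]
    }
    anc[[col]] <- cur
  }
  setkey(anc, term_id)
  structure(list(terms = terms[], ancestors = anc),
            class = "phenotype_hierarchy")
}

#' @export
print.phenotype_hierarchy <- function(x, ...) {
  tab <- x$terms[, .N, by = level][order(level)]
  cat(sprintf("<phenotype_hierarchy> %d terms (%s)\n", nrow(x$terms),
              paste(sprintf("L%d: %d", tab$level, tab$N), collapse = ", ")))
  invisible(x)
}

#' Read / write a phenotype hierarchy table
#'
#' Plain TSV with columns `term_id`, `name`, `level`, `parent_id`.
#'
#' @param path File path.
#' @return For `read_hierarchy`, a [phenotype_hierarchy()].
#' @export
read_hierarchy <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  phenotype_hierarchy(fread(path, sep = "\t", colClasses = "character",
                            na.strings = NULL))
}

#' @rdname read_hierarchy
#' @param hierarchy A `phenotype_hierarchy`.
#' @export
write_hierarchy <- function(hierarchy, path) {
  out <- copy(hierarchy$terms)
  out[, parent_id := fifelse(is.na(parent_id), "", parent_id)]
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Roll a term up to an ancestor level
#'
#' Returns, for each term, its unique ancestor at the requested level;
#' a term queried at its own level is returned unchanged.  Rolling up is
#' how reactions reported as near-synonymous specific terms (e.g. sibling
#' leaves under one disorder class) are grouped for analysis.
#'
#' @param hierarchy A [phenotype_hierarchy()].
#' @param term_id Character vector of term ids (vectorized).
#' @param level Target level, 1-4; must not exceed any queried term's level.
#' @return Character vector of ancestor term ids.
#' @export
ancestor_at_level <- function(hierarchy, term_id, level) {
  stopifnot(inherits(hierarchy, "phenotype_hierarchy"),
            length(level) == 1L, level %in% 1:4)
  ids <- as.character(term_id)   # a distinct name: J(term_id) would self-join
  anc <- hierarchy$ancestors[J(ids)]
  if (anyNA(anc$level)) {
    bad <- ids[is.na(anc$level)]
    stop(sprintf("unknown term(s): %s", paste(head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
  if (any(anc$level < level)) {
    bad <- anc$term_id[anc$level < level]
    stop(sprintf("term(s) above the requested level %d: %s", level,
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  anc[[paste0("anc", level)]]
}

# -- drug dictionary ----------------------------------------------------------

#' Construct a drug synonym dictionary
#'
#' One drug concept has a canonical name, a non-empty synonym set containing
#' the canonical name, and zero or more ATC class codes.  Synonyms are
#' stored both verbatim and normalized (see [normalize_string()]) because
#' all matching happens on the normalized forms.
#'
#' @param drugs A table with columns `drug_id`, `canonical_name`, `synonym`
#'   (one row per synonym) and `atc_codes` (";"-separated, may be empty).
#' @return An object of class `drug_dictionary`.
#' @export
drug_dictionary <- function(drugs) {
  drugs <- as.data.table(drugs)
  .assert_cols(drugs, c("drug_id", "canonical_name", "synonym", "atc_codes"),
               "drug dictionary")
  drugs <- drugs[, lapply(.SD, as.character)]
  concepts <- drugs[, .(canonical_name = canonical_name[1],
                        atc_codes = list(unique(unlist(.split_field(atc_codes))))),
                    by = drug_id]
  synonyms <- unique(drugs[, .(drug_id, synonym)])
  # canonical_name must itself be listed as a synonym
  chk <- merge(concepts[, .(drug_id, canonical_name)], synonyms, by = "drug_id")
  ok <- chk[, any(synonym == canonical_name), by = drug_id]
  if (!all(ok$V1))
    stop(sprintf("canonical_name missing from synonym set for: %s",
                 paste(head(ok$drug_id[!ok$V1], 5), collapse = ", ")),
         call. = FALSE)
  synonyms[, syn_norm := normalize_string(synonym)]
  synonyms <- synonyms[nzchar(syn_norm)]
  structure(list(concepts = concepts, synonyms = synonyms),
            class = "drug_dictionary")
}

#' @export
print.drug_dictionary <- function(x, ...) {
  cat(sprintf("<drug_dictionary> %d drugs, %d synonyms\n",
              nrow(x$concepts), nrow(x$synonyms)))
  invisible(x)
}

#' Read / write a drug dictionary table
#'
#' Plain TSV with one row per (drug, synonym) pair: columns `drug_id`,
#' `canonical_name`, `synonym`, `atc_codes` (";"-separated).
#'
#' @param path File path.
#' @return For `read_dictionary`, a [drug_dictionary()].
#' @export
read_dictionary <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  drug_dictionary(fread(path, sep = "\t", colClasses = "character",
                        na.strings = NULL))
}

#' @rdname read_dictionary
#' @param dictionary A `drug_dictionary`.
#' @export
write_dictionary <- function(dictionary, path) {
  atc <- dictionary$concepts[, .(drug_id,
                                 atc_codes = .join_field(atc_codes))]
  out <- merge(dictionary$synonyms[, .(drug_id, synonym)],
               dictionary$concepts[, .(drug_id, canonical_name)],
               by = "drug_id")
  out <- merge(out, atc, by = "drug_id")
  setcolorder(out, c("drug_id", "canonical_name", "synonym", "atc_codes"))
  fwrite(out, path, sep = "\t")
  invisible(path)
}

# -- drug-protein links -------------------------------------------------------

.LINK_ROLES   <- c("target", "enzyme", "carrier", "transporter")
.LINK_ACTIONS <- c("agonist", "antagonist", "unknown")

#' Construct a drug-protein link table
#'
#' Each row links a drug to a protein in one `role` (target, metabolizing
#' enzyme, carrier or transporter) with a pharmacologic `action` (agonist,
#' antagonist or unknown).  `(drug_id, protein_id, role)` is unique.
#'
#' @param links A table with columns `drug_id`, `protein_id`, `role`,
#'   `action`.
#' @return A validated `target_links` `data.table`.
#' @export
target_links <- function(links) {
  links <- as.data.table(links)
  .assert_cols(links, c("drug_id", "protein_id", "role", "action"), "link table")
  links <- links[, lapply(.SD, as.character)]
  bad_role <- setdiff(unique(links$role), .LINK_ROLES)
  if (length(bad_role))
    stop(sprintf("unknown role(s): %s", paste(bad_role, collapse = ", ")),
         call. = FALSE)
  bad_act <- setdiff(unique(links$action), .LINK_ACTIONS)
  if (length(bad_act))
    stop(sprintf("unknown action(s): %s", paste(bad_act, collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(links, by = c("drug_id", "protein_id", "role")))
    stop("duplicate (drug_id, protein_id, role) in link table", call. = FALSE)
  setattr(links, "class", unique(c("target_links", class(links))))
  links[]
}

#' Read / write a drug-protein link table
#'
#' Plain TSV with columns `drug_id`, `protein_id`, `role`, `action`.
#'
#' @param path File path.
#' @return For `read_links`, a validated `target_links` table.
#' @export
read_links <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  target_links(fread(path, sep = "\t", colClasses = "character",
                     na.strings = NULL))
}

#' @rdname read_links
#' @param links A `target_links` table.
#' @export
write_links <- function(links, path) {
  fwrite(links[, .(drug_id, protein_id, role, action)], path, sep = "\t")
  invisible(path)
}

# -- protein annotations ------------------------------------------------------

#' Construct a protein annotation table
#'
#' One row per protein: gene symbol and pathway memberships.
#'
#' @param annotations A table with columns `protein_id`, `gene_symbol`,
#'   `pathway_ids` (";"-separated or a list-column).
#' @return A validated `protein_annotations` `data.table` with a
#'   `pathway_ids` list-column.
#' @export
protein_annotations <- function(annotations) {
  annotations <- as.data.table(annotations)
  .assert_cols(annotations, c("protein_id", "gene_symbol", "pathway_ids"),
               "protein annotations")
  if (!is.list(annotations$pathway_ids))
    annotations[, pathway_ids := .split_field(as.character(pathway_ids))]
  annotations[, `:=`(protein_id = as.character(protein_id),
                     gene_symbol = as.character(gene_symbol))]
  if (anyDuplicated(annotations$protein_id))
    stop("duplicate protein_id in annotations", call. = FALSE)
  setattr(annotations, "class",
          unique(c("protein_annotations", class(annotations))))
  annotations[]
}

#' Read / write a protein annotation table
#'
#' Plain TSV with columns `protein_id`, `gene_symbol`, `pathway_ids`
#' (";"-separated).
#'
#' @param path File path.
#' @return For `read_annotations`, a validated annotation table.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  protein_annotations(fread(path, sep = "\t", colClasses = "character",
                            na.strings = NULL))
}

#' @rdname read_annotations
#' @param annotations A `protein_annotations` table.
#' @export
write_annotations <- function(annotations, path) {
  out <- annotations[, .(protein_id, gene_symbol,
                         pathway_ids = .join_field(pathway_ids))]
  fwrite(out, path, sep = "\t")
  invisible(path)
}
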