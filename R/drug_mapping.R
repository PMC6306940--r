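# Stepwise normalization of verbatim drug-mention strings against a synonym
# dictionary: exact match, then token-part match, then bounded edit-distance
# match, with a blacklist consulted before every phase.

#' Canonicalize a string for dictionary matching
#'
#' Case-folds, replaces every non-alphanumeric character (punctuation,
#' trademark signs, odd whitespace) with a single space, collapses runs of
#' spaces and trims.  Deterministic and idempotent; all dictionary matching
#' operates on this form.
#'
#' @param s Character vector.
#' @return Character vector of the same length.
#' @export
#' @examples
#' normalize_string("  Aspirin®  ")   # "aspirin"
normalize_string <- function(s) {
  s <- tolower(as.character(s))
  s <- gsub("[^a-z0-9]+", " ", s)
  trimws(gsub(" +", " ", s))
}

#' Mapping stage levels
#'
#' @keywords internal
.MAP_STAGES <- c("exact", "part", "fuzzy", "blacklist", "unmapped")

.norm_blacklist <- function(blacklist) {
  unique(normalize_string(blacklist))
}

# phrase-level separators marking multi-drug mentions; split on the RAW
# string because normalization erases "+" and "/"
.split_parts <- function(verbatim) {
  parts <- strsplit(verbatim, "(?i)[+/]|\\band\\b", perl = TRUE)[[1]]
  parts <- normalize_string(parts)
  parts[nzchar(parts)]
}

.empty_result <- function(verbatim, stage, distance = NA_integer_) {
  list(verbatim = verbatim, matches = character(0), stage = stage,
       distance = distance, ambiguous = FALSE)
}

# plain-vector view of the synonym table; built once per corpus mapping to
# avoid per-name data.table overhead
.prep_dict <- function(dictionary, blacklist_norm, min_part_nchar) {
  syn <- dictionary$synonyms
  list(syn = syn$syn_norm, drug = syn$drug_id, nch = nchar(syn$syn_norm),
       part_ok = nchar(syn$syn_norm) >= min_part_nchar &
         !(syn$syn_norm %in% blacklist_norm),
       has_space = grepl(" ", syn$syn_norm, fixed = TRUE))
}

# map one already-normalized single-drug phrase (no part splitting)
.map_phrase <- function(norm, prep, blacklist_norm, max_distance,
                        min_part_nchar) {
  if (norm %in% blacklist_norm)
    return(list(matches = character(0), stage = "blacklist",
                distance = NA_integer_))
  hit <- prep$drug[prep$syn == norm]
  if (length(hit))
    return(list(matches = unique(hit), stage = "exact", distance = 0L))
  # token-part phase: a synonym (>= min_part_nchar chars) appearing as a
  # contiguous token subsequence of the mention; for a single-token mention
  # this reduces to the exact phase, so only multi-token mentions are scanned
  if (grepl(" ", norm, fixed = TRUE)) {
    toks <- strsplit(norm, " ", fixed = TRUE)[[1]]
    found <- prep$part_ok & ((!prep$has_space & prep$syn %in% toks) |
                               (prep$has_space &
                                  vapply(paste0(" ", prep$syn, " "),
                                         grepl,
                                         x = paste0(" ", norm, " "),
                                         fixed = TRUE, logical(1))))
    if (any(found))
      return(list(matches = unique(prep$drug[found]), stage = "part",
                  distance = 0L))
  }
  # bounded-similarity phase: minimum Levenshtein distance over all synonyms,
  # refusing anything beyond max_distance
  d <- as.integer(adist(norm, prep$syn)[1L, ])
  dmin <- min(d)
  if (is.finite(dmin) && dmin <= max_distance) {
    hits <- unique(prep$drug[d == dmin])
    return(list(matches = hits, stage = "fuzzy", distance = dmin))
  }
  list(matches = character(0), stage = "unmapped", distance = dmin)
}

#' Map one verbatim drug mention to drug concepts
#'
#' Implements the stepwise mapping procedure: (1) a blacklist of irrelevant
#' tokens (e.g. "UNKNOWN", "UNK") is consulted before every phase; (2) exact
#' match of the normalized mention against normalized synonyms; (3) a
#' token-part phase matching whole synonyms embedded in longer phrases
#' (handles "TYLENOL 500MG TABLET"; matches shorter than `min_part_nchar`
#' characters are rejected as spurious); (4) a bounded-similarity phase
#' returning the minimum-edit-distance synonym's drug(s), refusing any
#' candidate differing by more than `max_distance` (default 5) characters.
#' Multi-drug phrases (parts separated by "+", "/" or " and ") are split and
#' each part mapped; the union of matches is returned.
#'
#' @param verbatim The mention string as reported.
#' @param dictionary A [drug_dictionary()].
#' @param blacklist Character vector of terms never to match.
#' @param max_distance Maximum Levenshtein distance for the fuzzy phase.
#' @param min_part_nchar Minimum length of a synonym matched in the part
#'   phase.
#' @return A `mapping_result`: list with `verbatim`, `matches` (drug ids),
#'   `stage` (one of exact/part/fuzzy/blacklist/unmapped), `distance`
#'   (edits; 0 for exact/part) and `ambiguous` (more than one drug).
#' @export
map_name <- function(verbatim, dictionary, blacklist = c("UNKNOWN", "UNK"),
                     max_distance = 5L, min_part_nchar = 4L, .prep = NULL) {
  stopifnot(inherits(dictionary, "drug_dictionary"),
            nrow(dictionary$synonyms) > 0L)
  blacklist_norm <- .norm_blacklist(blacklist)
  if (is.null(.prep))
    .prep <- .prep_dict(dictionary, blacklist_norm, min_part_nchar)
  norm <- normalize_string(verbatim)
  if (!nzchar(norm)) {
    res <- .empty_result(verbatim, "unmapped")
    class(res) <- "mapping_result"
    return(res)
  }
  if (norm %in% blacklist_norm) {
    res <- .empty_result(verbatim, "blacklist")
    class(res) <- "mapping_result"
    return(res)
  }
  first <- .map_phrase(norm, .prep, blacklist_norm, max_distance,
                       min_part_nchar)
  res <- first
  if (!length(first$matches) || first$stage == "unmapped") {
    parts <- .split_parts(verbatim)
    if (length(parts) > 1L) {
      sub <- lapply(parts, .map_phrase, prep = .prep,
                    blacklist_norm = blacklist_norm,
                    max_distance = max_distance,
                    min_part_nchar = min_part_nchar)
      matched <- Filter(function(x) length(x$matches) > 0L, sub)
      if (length(matched)) {
        stages <- vapply(matched, `[[`, character(1), "stage")
        dists  <- vapply(matched, `[[`, integer(1), "distance")
        res <- list(matches = unique(unlist(lapply(matched, `[[`, "matches"))),
                    stage = .MAP_STAGES[max(match(stages, .MAP_STAGES))],
                    distance = max(dists))
      }
    }
  }
  out <- list(verbatim = verbatim, matches = res$matches, stage = res$stage,
              distance = res$distance,
              ambiguous = length(res$matches) > 1L)
  class(out) <- "mapping_result"
  out
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(sprintf("<mapping_result> '%s' -> [%s] stage=%s distance=%s%s\n",
              x$verbatim, paste(x$matches, collapse = ","), x$stage,
              ifelse(is.na(x$distance), "-", x$distance),
              if (x$ambiguous) " (ambiguous)" else ""))
  invisible(x)
}

#' Map every mention of a corpus
#'
#' Maps each distinct verbatim string once (mapping is a pure function of
#' the string, the dictionary and the blacklist, so corpus order is
#' irrelevant), annotates the corpus with per-case mapped drug ids, and
#' computes coverage statistics: the fraction of distinct non-blacklist
#' names with at least one match, and the fraction of cases with at least
#' one mapped mention.
#'
#' Ambiguous fuzzy matches (several drugs at the same minimal distance) are
#' excluded from the per-case `drug_ids` expansion unless
#' `include_ambiguous = TRUE`; exact and part-stage ambiguity (genuine
#' multi-drug phrases) is always kept.
#'
#' @param corpus An [ae_corpus()].
#' @param dictionary A [drug_dictionary()].
#' @param blacklist Character vector of terms never to match.
#' @param max_distance,min_part_nchar Passed to [map_name()].
#' @param include_ambiguous Keep drugs from ambiguous fuzzy matches.
#' @return A list of class `mapped_corpus`:
#'   \describe{
#'     \item{corpus}{the input corpus with a `drug_ids` list-column added}
#'     \item{mentions}{one row per distinct verbatim string with its
#'       mapping result}
#'     \item{coverage}{`frac_names_mapped`, `frac_reports_mapped`}
#'     \item{unmapped}{names that failed to map, with their nearest-synonym
#'       distance}
#'   }
#' @export
map_corpus <- function(corpus, dictionary, blacklist = c("UNKNOWN", "UNK"),
                       max_distance = 5L, min_part_nchar = 4L,
                       include_ambiguous = FALSE) {
  stopifnot(inherits(corpus, "ae_corpus"))
  verbs <- unique(unlist(corpus$drug_mentions))
  if (is.null(verbs)) verbs <- character(0)
  prep <- .prep_dict(dictionary, .norm_blacklist(blacklist), min_part_nchar)
  results <- lapply(verbs, map_name, dictionary = dictionary,
                    blacklist = blacklist, max_distance = max_distance,
                    min_part_nchar = min_part_nchar, .prep = prep)
  mentions <- data.table(
    verbatim  = verbs,
    stage     = vapply(results, `[[`, character(1), "stage"),
    distance  = vapply(results, `[[`, integer(1), "distance"),
    ambiguous = vapply(results, `[[`, logical(1), "ambiguous"),
    matches   = lapply(results, `[[`, "matches")
  )
  usable <- mentions$matches
  drop <- mentions$ambiguous & mentions$stage == "fuzzy" & !include_ambiguous
  usable[drop] <- list(character(0))
  lut <- setNames(usable, mentions$verbatim)
  out <- copy(corpus)
  out[, drug_ids := lapply(drug_mentions, function(m) {
    if (!length(m)) character(0) else sort(unique(unlist(lut[m])))
  })]
  setattr(out, "class", unique(c("ae_corpus", class(out))))
  considered <- mentions[stage != "blacklist"]
  n_mapped <- considered[, sum(vapply(matches, length, integer(1)) > 0L)]
  frac_names <- if (nrow(considered)) n_mapped / nrow(considered) else NA_real_
  case_mapped <- vapply(out$drug_ids, length, integer(1)) > 0L
  frac_reports <- if (nrow(out)) mean(case_mapped) else NA_real_
  unmapped <- mentions[stage == "unmapped",
                       .(verbatim, nearest_distance = distance)]
  structure(list(corpus = out[], mentions = mentions,
                 coverage = list(frac_names_mapped = frac_names,
                                 frac_reports_mapped = frac_reports),
                 unmapped = unmapped),
            class = "mapped_corpus")
}

#' @export
print.mapped_corpus <- function(x, ...) {
  cat(sprintf(paste0("<mapped_corpus> %d cases; %d distinct names; ",
                     "%.1f%% names mapped, %.1f%% reports mapped\n"),
              nrow(x$corpus), nrow(x$mentions),
              100 * x$coverage$frac_names_mapped,
              100 * x$coverage$frac_reports_mapped))
  invisible(x)
}
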