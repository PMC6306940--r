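# Expansion of mapped drugs to molecular annotations per case, the
# clean-target filter, temporal slices and cohort selection.

.ENTITY_KINDS <- c("drug", "target", "enzyme", "carrier", "transporter",
                   "pathway", "atc_class")

.role_lut <- function(links, role_name) {
  sub <- links[role == role_name]
  split(sub$protein_id, sub$drug_id)
}

#' Annotate a mapped corpus with molecular entities
#'
#' Expands each case's mapped `drug_ids` to the union of linked targets,
#' metabolizing enzymes, carriers and transporters, to pathways of those
#' targets, and to ATC classes of the drugs.  Cases with no mapped drug keep
#' empty molecular sets but remain in the corpus: they still contribute to
#' the unexposed cells of every contingency table.  Per-target pharmacologic
#' actions are recorded as `"protein:action"` strings for
#' mechanism-stratified profiling.
#'
#' @param mapped A `mapped_corpus` from [map_corpus()], or an `ae_corpus`
#'   that already carries a `drug_ids` list-column.
#' @param links A [target_links()] table.  Every `drug_id` appearing in the
#'   corpus mapping must be known to the dictionary that produced it; a link
#'   whose `drug_id` never occurs is allowed (not all drugs are reported).
#' @param annotations Optional [protein_annotations()] for pathway expansion.
#' @param dictionary Optional [drug_dictionary()] for ATC class expansion.
#' @return The corpus with list-columns `drug_ids`, `target_ids`,
#'   `enzyme_ids`, `carrier_ids`, `transporter_ids`, `pathway_ids`,
#'   `atc_classes`, `target_actions` added; class `annotated_corpus`.
#' @export
annotate_cases <- function(mapped, links, annotations = NULL,
                           dictionary = NULL) {
  corpus <- if (inherits(mapped, "mapped_corpus")) mapped$corpus else mapped
  stopifnot(inherits(corpus, "ae_corpus"))
  if (!"drug_ids" %in% names(corpus))
    stop("corpus has no drug_ids column; run map_corpus() first", call. = FALSE)
  stopifnot(inherits(links, "target_links"))
  if (!is.null(dictionary)) {
    unknown <- setdiff(unique(links$drug_id), dictionary$concepts$drug_id)
    if (length(unknown))
      stop(sprintf("link table references drug_id(s) unknown to the dictionary: %s",
                   paste(head(unknown, 5), collapse = ", ")), call. = FALSE)
  }
  out <- copy(corpus)

  luts <- lapply(c(target = "target", enzyme = "enzyme", carrier = "carrier",
                   transporter = "transporter"), .role_lut, links = links)
  expand <- function(ids, lut) {
    if (!length(ids)) return(character(0))
    .sunion(unlist(lut[ids], use.names = FALSE))
  }
  out[, target_ids      := lapply(drug_ids, expand, lut = luts$target)]
  out[, enzyme_ids      := lapply(drug_ids, expand, lut = luts$enzyme)]
  out[, carrier_ids     := lapply(drug_ids, expand, lut = luts$carrier)]
  out[, transporter_ids := lapply(drug_ids, expand, lut = luts$transporter)]

  if (!is.null(annotations)) {
    p2pw <- setNames(annotations$pathway_ids, annotations$protein_id)
    out[, pathway_ids := lapply(target_ids, function(tg) {
      if (!length(tg)) character(0)
      else .sunion(unlist(p2pw[tg], use.names = FALSE))
    })]
  } else out[, pathway_ids := rep(list(character(0)), .N)]

  if (!is.null(dictionary)) {
    d2atc <- setNames(dictionary$concepts$atc_codes,
                      dictionary$concepts$drug_id)
    out[, atc_classes := lapply(drug_ids, function(ds) {
      if (!length(ds)) character(0)
      else .sunion(unlist(d2atc[ds], use.names = FALSE))
    })]
  } else out[, atc_classes := rep(list(character(0)), .N)]

  tlinks <- links[role == "target"]
  act_lut <- split(paste0(tlinks$protein_id, ":", tlinks$action),
                   tlinks$drug_id)
  out[, target_actions := lapply(drug_ids, expand, lut = act_lut)]

  setattr(out, "class",
          unique(c("annotated_corpus", "ae_corpus", class(out))))
  out[]
}

#' Clean drug targets
#'
#' A protein is a "clean" target when it is listed as the target of at least
#' one drug and never additionally as a metabolizing enzyme, carrier or
#' transporter of any drug.  Restricting profiling to clean targets avoids
#' attributing phenotypes to proteins whose co-mention merely reflects drug
#' metabolism or transport.
#'
#' @param links A [target_links()] table.
#' @return Sorted character vector of clean protein ids.
#' @export
clean_targets <- function(links) {
  stopifnot(inherits(links, "target_links"))
  as_target <- unique(links[role == "target", protein_id])
  other     <- unique(links[role != "target", protein_id])
  sort(setdiff(as_target, other))
}

#' Keep cases reported strictly before a cutoff date
#'
#' Used for prospective-retrospective analyses: profile an entity on the
#' data slice available before some external event (e.g. a drug approval)
#' and compare with what was observed later.  Cases without a report date
#' are dropped from the slice.
#'
#' @param corpus An `ae_corpus`.
#' @param cutoff_date A `Date` (or string coercible to one).
#' @return The filtered corpus (same class).
#' @export
slice_by_date <- function(corpus, cutoff_date) {
  stopifnot(inherits(corpus, "ae_corpus"))
  cutoff <- as.Date(cutoff_date)
  if (is.na(cutoff)) stop("cutoff_date is not a valid date", call. = FALSE)
  keep <- !is.na(corpus$report_date) & corpus$report_date < cutoff
  out <- corpus[keep]
  setattr(out, "class", class(corpus))
  out[]
}

#' Specify a patient cohort
#'
#' A conjunction of optional criteria; at least one must be set.
#' `indication_term`/`indication_level` selects cases any of whose
#' indications rolls up to the term at that hierarchy level.  `atc_prefix`
#' selects by drug-class code prefix (so `"C07A"` covers all its children),
#' with `atc_present = FALSE` selecting the complement.  `target_id`
#' selects by target engagement (optionally restricted to an `action`),
#' again with a presence flag.  `date_from`/`date_to` bound the report date
#' (inclusive; dateless cases never satisfy a date criterion).
#'
#' @param indication_term Term id, or NULL.
#' @param indication_level Level of `indication_term` (1-4).
#' @param atc_prefix ATC code prefix, or NULL.
#' @param atc_present Logical; require presence (TRUE) or absence (FALSE).
#' @param target_id Protein id, or NULL.
#' @param target_present Logical; require presence or absence.
#' @param action Optional action filter for the target criterion
#'   ("agonist"/"antagonist"/"unknown").
#' @param date_from,date_to Optional date bounds.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(indication_term = NULL, indication_level = NULL,
                        atc_prefix = NULL, atc_present = TRUE,
                        target_id = NULL, target_present = TRUE,
                        action = NULL, date_from = NULL, date_to = NULL) {
  spec <- list(indication_term = indication_term,
               indication_level = indication_level,
               atc_prefix = atc_prefix, atc_present = isTRUE(atc_present),
               target_id = target_id, target_present = isTRUE(target_present),
               action = action,
               date_from = if (!is.null(date_from)) as.Date(date_from),
               date_to = if (!is.null(date_to)) as.Date(date_to))
  if (is.null(spec$indication_term) && is.null(spec$atc_prefix) &&
      is.null(spec$target_id) && is.null(spec$date_from) &&
      is.null(spec$date_to))
    stop("cohort_spec: at least one criterion must be set", call. = FALSE)
  if (!is.null(spec$indication_term) && is.null(spec$indication_level))
    stop("cohort_spec: indication_term requires indication_level", call. = FALSE)
  if (!is.null(spec$action) &&
      !spec$action %in% c("agonist", "antagonist", "unknown"))
    stop("cohort_spec: unknown action", call. = FALSE)
  structure(spec, class = "cohort_spec")
}

.cohort_mask <- function(corpus, spec, hierarchy = NULL) {
  keep <- rep(TRUE, nrow(corpus))
  if (!is.null(spec$indication_term)) {
    if (is.null(hierarchy))
      stop("an indication criterion requires the phenotype hierarchy",
           call. = FALSE)
    if (!spec$indication_term %in% hierarchy$terms$term_id)
      stop(sprintf("unknown indication term: %s", spec$indication_term),
           call. = FALSE)
    lvl <- spec$indication_level
    term <- spec$indication_term
    keep <- keep & vapply(corpus$indications, function(ind) {
      if (!length(ind)) return(FALSE)
      ok <- hierarchy$ancestors[J(ind)]
      any(ok$level >= lvl & ok[[paste0("anc", lvl)]] == term, na.rm = TRUE)
    }, logical(1))
  }
  if (!is.null(spec$atc_prefix)) {
    if (!"atc_classes" %in% names(corpus))
      stop("an ATC criterion requires an annotated corpus", call. = FALSE)
    has <- vapply(corpus$atc_classes, function(a) {
      length(a) > 0L && any(startsWith(a, spec$atc_prefix))
    }, logical(1))
    keep <- keep & (has == spec$atc_present)
  }
  if (!is.null(spec$target_id)) {
    if (!"target_ids" %in% names(corpus))
      stop("a target criterion requires an annotated corpus", call. = FALSE)
    if (is.null(spec$action)) {
      has <- vapply(corpus$target_ids, function(t) spec$target_id %in% t,
                    logical(1))
    } else {
      tag <- paste0(spec$target_id, ":", spec$action)
      has <- vapply(corpus$target_actions, function(t) tag %in% t, logical(1))
    }
    keep <- keep & (has == spec$target_present)
  }
  if (!is.null(spec$date_from))
    keep <- keep & !is.na(corpus$report_date) &
      corpus$report_date >= spec$date_from
  if (!is.null(spec$date_to))
    keep <- keep & !is.na(corpus$report_date) &
      corpus$report_date <= spec$date_to
  keep
}

#' Partition a corpus into a cohort and its complement
#'
#' @param corpus An (annotated) `ae_corpus`.
#' @param spec A [cohort_spec()].
#' @param hierarchy A [phenotype_hierarchy()]; required when the spec has an
#'   indication criterion.
#' @return List with elements `cohort` and `complement`; together they are
#'   an exact partition of the input.
#' @export
select_cohort <- function(corpus, spec, hierarchy = NULL) {
  stopifnot(inherits(corpus, "ae_corpus"), inherits(spec, "cohort_spec"))
  keep <- .cohort_mask(corpus, spec, hierarchy)
  cls <- class(corpus)
  inc <- corpus[keep];  setattr(inc, "class", cls)
  out <- corpus[!keep]; setattr(out, "class", cls)
  list(cohort = inc[], complement = out[])
}

# logical exposure vector for one entity over an annotated corpus
.exposure_vec <- function(corpus, entity_kind, entity_id) {
  entity_kind <- match.arg(entity_kind, .ENTITY_KINDS)
  col <- switch(entity_kind,
                drug = "drug_ids", target = "target_ids",
                enzyme = "enzyme_ids", carrier = "carrier_ids",
                transporter = "transporter_ids", pathway = "pathway_ids",
                atc_class = "atc_classes")
  if (!col %in% names(corpus))
    stop(sprintf("corpus lacks the '%s' annotation; run annotate_cases()", col),
         call. = FALSE)
  if (entity_kind == "atc_class")
    vapply(corpus[[col]],
           function(v) length(v) > 0L && any(startsWith(v, entity_id)),
           logical(1))
  else
    vapply(corpus[[col]], function(v) entity_id %in% v, logical(1))
}
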