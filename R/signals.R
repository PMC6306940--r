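# Disproportionality statistics: 2x2 contingency construction, the
# proportional reporting ratio (PRR), Fisher's exact test,
# Benjamini-Hochberg q-values, and entity-event screening/profiling.

.EVENT_KINDS <- c("reaction", "indication", "outcome")

#' Construct a 2x2 contingency table
#'
#' Cell semantics for an (entity, event) pair over a case corpus:
#' `a` = cases with both entity and event, `b` = entity without event,
#' `c` = event without entity, `d` = neither.  `N = a+b+c+d` equals the
#' corpus size when built from a corpus.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return A `contingency_table` object.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("contingency cells must be non-negative integers", call. = FALSE)
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 d = as.numeric(d), N = as.numeric(a + b + c + d)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("entity", "no entity"),
                              c("event", "no event")))
  print(m)
  invisible(x)
}

#' Proportional reporting ratio
#'
#' `PRR = a(c+d) / (c(a+b))`, identically the ratio of the event's
#' reporting proportion among entity cases, `a/(a+b)`, to that among
#' non-entity cases, `c/(c+d)`.  No continuity correction is applied.  With
#' `permissive = FALSE` (default) a degenerate table raises; with
#' `permissive = TRUE`, `c = 0` yields `Inf` and `a+b = 0` yields `NaN`.
#'
#' @param table A [contingency_table()].
#' @param permissive Return Inf/NaN instead of raising on degenerate
#'   tables.
#' @return The PRR as a double.
#' @export
prr <- function(table, permissive = FALSE) {
  stopifnot(inherits(table, "contingency_table"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  if (!permissive) {
    if (a + b == 0) stop("PRR undefined: no entity-exposed cases (a+b = 0)",
                         call. = FALSE)
    if (c == 0) stop("PRR undefined: no comparator events (c = 0)",
                     call. = FALSE)
  }
  if (a + b == 0) return(NaN)
  if (c == 0) return(if (a > 0) Inf else NaN)
  a * (c + d) / (c * (a + b))
}

# vectorized permissive PRR for bulk screens
.prr_vec <- function(a, b, c, d) {
  out <- a * (c + d) / (c * (a + b))
  out[a + b == 0] <- NaN
  out[c == 0 & a > 0 & a + b > 0] <- Inf
  out[c == 0 & a == 0] <- NaN
  out
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test with margins fixed.  `sided = "one"` gives the
#' upper tail (over-representation of the event among entity cases);
#' `sided = "two"` (default) uses the minimum-likelihood rule: the sum of
#' probabilities of all tables with the same margins whose probability does
#' not exceed the observed table's.
#'
#' @param table A [contingency_table()].
#' @param sided `"two"` (default) or `"one"`.
#' @return The p-value.
#' @export
fisher_exact <- function(table, sided = c("two", "one")) {
  sided <- match.arg(sided)
  stopifnot(inherits(table, "contingency_table"))
  .fisher_p(table$a, table$b, table$c, table$d, sided)
}

.fisher_p <- function(a, b, c, d, sided = "two") {
  m <- a + b            # entity cases
  n <- c + d            # non-entity cases
  k <- a + c            # event cases
  lo <- max(0, k - n)
  hi <- min(k, m)
  support <- lo:hi
  dens <- dhyper(support, m, n, k)
  if (sided == "one") return(min(1, sum(dens[support >= a])))
  dobs <- dens[support == a]
  min(1, sum(dens[dens <= dobs * (1 + 1e-7)]))
}

.fisher_p_vec <- function(a, b, c, d, sided = "two") {
  vapply(seq_along(a),
         function(i) .fisher_p(a[i], b[i], c[i], d[i], sided),
         numeric(1))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: with order statistics `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} p_(j) m / j`, capped at 1, mapped back to input
#' order.  `method = "storey"` multiplies by an estimated null proportion
#' `pi0 = min(1, mean(p > 0.5) / 0.5)` (the BH default corresponds to
#' `pi0 = 1` and is conservative).
#'
#' q-values are always computed within one screen or profile call, never
#' across calls; re-screening a different scope changes them.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` (default) or `"storey"`.
#' @return Numeric vector of q-values, same order as `p`.
#' @export
qvalues <- function(p, method = c("BH", "storey")) {
  method <- match.arg(method)
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  if (method == "storey") {
    pi0 <- min(1, mean(p > 0.5) / 0.5)
    if (pi0 <= 0) pi0 <- 1 / m        # degenerate: all p tiny
    q <- pmin(q * pi0, 1)
  }
  q
}

#' Thresholds that flag a signal
#'
#' Defaults follow the reporting conventions used for target-phenotype
#' screens: an entity must be linked to at least 500 cases to be profiled
#' at all (`min_entity_support`); an association is `supported` with at
#' least 10 co-occurring cases, `strong` with PRR >= 2, and `significant`
#' with q < 0.05.
#'
#' @param min_entity_support Minimum cases linked to the entity.
#' @param min_cooccurrence Minimum `a` for the supported flag.
#' @param prr_threshold Minimum PRR for the strong flag.
#' @param q_threshold Maximum q for the significant flag (exclusive).
#' @return A `signal_filter` object.
#' @export
signal_filter <- function(min_entity_support = 500, min_cooccurrence = 10,
                          prr_threshold = 2, q_threshold = 0.05) {
  vals <- c(min_entity_support, min_cooccurrence, prr_threshold, q_threshold)
  if (any(is.na(vals)) || any(vals < 0))
    stop("filter thresholds must be non-negative", call. = FALSE)
  structure(list(min_entity_support = min_entity_support,
                 min_cooccurrence = min_cooccurrence,
                 prr_threshold = prr_threshold,
                 q_threshold = q_threshold),
            class = "signal_filter")
}

# long (row index, event_id) table of case-event incidences after rollup
.event_cases <- function(corpus, hierarchy, event_kind, event_level) {
  event_kind <- match.arg(event_kind, .EVENT_KINDS)
  if (event_kind == "outcome") {
    vals <- corpus$outcomes
  } else {
    vals <- corpus[[if (event_kind == "reaction") "reactions" else "indications"]]
  }
  n <- lengths(vals)
  long <- data.table(idx = rep(seq_along(vals), n),
                     term = unlist(vals, use.names = FALSE))
  if (!nrow(long)) return(data.table(idx = integer(0), event_id = character(0)))
  if (event_kind == "outcome") {
    setnames(long, "term", "event_id")
    return(unique(long))
  }
  if (is.null(hierarchy))
    stop("reaction/indication events require the phenotype hierarchy",
         call. = FALSE)
  anc <- hierarchy$ancestors[J(long$term)]
  if (anyNA(anc$level))
    stop(sprintf("corpus references unknown term(s): %s",
                 paste(head(unique(long$term[is.na(anc$level)]), 5),
                       collapse = ", ")), call. = FALSE)
  long[, event_id := anc[[paste0("anc", event_level)]]]
  unique(long[!is.na(event_id), .(idx, event_id)])
}

.validate_event <- function(hierarchy, event_kind, event_id, event_level) {
  if (event_kind == "outcome") {
    if (!event_id %in% .OUTCOME_CODES)
      stop(sprintf("unknown outcome code: %s", event_id), call. = FALSE)
    return(invisible(TRUE))
  }
  if (is.null(hierarchy))
    stop("reaction/indication events require the phenotype hierarchy",
         call. = FALSE)
  row <- hierarchy$terms[term_id == event_id]
  if (!nrow(row))
    stop(sprintf("unknown event term: %s", event_id), call. = FALSE)
  if (row$level != event_level)
    stop(sprintf("event term %s is at level %d, not the requested level %d",
                 event_id, row$level, event_level), call. = FALSE)
  invisible(TRUE)
}

#' Build the contingency table of one (entity, event) pair
#'
#' A case counts as having the event when any of its reaction (or
#' indication) terms rolls up to `event_id` at `event_level`; entity
#' presence comes from the annotated per-case sets.  Every case falls in
#' exactly one cell, so the cells sum to the corpus size.
#'
#' @param corpus An annotated corpus from [annotate_cases()].
#' @param entity_kind One of drug, target, enzyme, carrier, transporter,
#'   pathway, atc_class.
#' @param entity_id The entity's id (for `atc_class`, a code prefix).
#' @param event_kind One of reaction, indication, outcome.
#' @param event_id Term id at `event_level` (or an outcome code).
#' @param event_level Hierarchy level of the event, 1-4 (ignored for
#'   outcomes).
#' @param hierarchy The [phenotype_hierarchy()] (required except for
#'   outcomes).
#' @return A [contingency_table()].
#' @export
build_contingency <- function(corpus, entity_kind, entity_id, event_kind,
                              event_id, event_level = 4L, hierarchy = NULL) {
  event_kind <- match.arg(event_kind, .EVENT_KINDS)
  .validate_event(hierarchy, event_kind, event_id, event_level)
  exposed <- .exposure_vec(corpus, entity_kind, entity_id)
  ev <- .event_cases(corpus, hierarchy, event_kind, event_level)
  has_event <- rep(FALSE, nrow(corpus))
  has_event[ev$idx[ev$event_id == event_id]] <- TRUE
  contingency_table(sum(exposed & has_event), sum(exposed & !has_event),
                    sum(!exposed & has_event), sum(!exposed & !has_event))
}

# flags + ordering shared by profiles and screens
.finish_signals <- function(dt, filter, q_method = "BH") {
  dt[, prr := .prr_vec(a, b, c, d)]
  dt[, p := .fisher_p_vec(a, b, c, d)]
  dt[, q := qvalues(p, method = q_method)]
  dt[, supported := a >= filter$min_cooccurrence]
  dt[, strong := !is.nan(prr) & prr >= filter$prr_threshold]
  dt[, significant := q < filter$q_threshold]
  dt[, flagged := supported & strong & significant]
  dt
}

.rank_profile <- function(dt) {
  setorderv(dt, c("flagged", "prr", "a", "event_id"),
            order = c(-1L, -1L, -1L, 1L), na.last = TRUE)
  dt
}

#' Phenotype profile of one entity
#'
#' Builds the contingency table of the entity against every event observed
#' together with it at the requested hierarchy level, computes PRR,
#' Fisher's exact p and q-values (over this profile's own p-values), and
#' ranks records: flagged associations (supported, strong and significant)
#' first, by descending PRR, ties broken by `a` then `event_id`.
#'
#' @inheritParams build_contingency
#' @param filter A [signal_filter()]; the entity must be linked to at least
#'   `min_entity_support` cases.
#' @param q_method Passed to [qvalues()].
#' @return A `data.table` of signal records: entity, event, a-d, prr, p, q
#'   and the three flags.
#' @export
profile_entity <- function(corpus, entity_kind, entity_id, event_kind,
                           event_level = 4L, hierarchy = NULL,
                           filter = signal_filter(), q_method = "BH") {
  exposed <- .exposure_vec(corpus, entity_kind, entity_id)
  support <- sum(exposed)
  if (support < filter$min_entity_support)
    stop(sprintf("entity %s linked to %d cases, below min_entity_support = %s",
                 entity_id, support,
                 format(filter$min_entity_support)), call. = FALSE)
  .profile_from_exposure(corpus, exposed, entity_kind, entity_id, event_kind,
                         event_level, hierarchy, filter, q_method)
}

.profile_from_exposure <- function(corpus, exposed, entity_kind, entity_id,
                                   event_kind, event_level, hierarchy,
                                   filter, q_method = "BH") {
  ev <- .event_cases(corpus, hierarchy, event_kind, event_level)
  n_total <- nrow(corpus)
  n_exp <- sum(exposed)
  totals <- ev[, .(n_event = .N), by = event_id]
  with_ent <- ev[exposed[idx] == TRUE, .(a = .N), by = event_id]
  dt <- merge(with_ent, totals, by = "event_id", all.x = TRUE)
  if (!nrow(dt))
    return(.finish_signals(
      data.table(entity_id = character(0), entity_kind = character(0),
                 event_id = character(0), event_kind = character(0),
                 event_level = integer(0), a = numeric(0), b = numeric(0),
                 c = numeric(0), d = numeric(0)), filter, q_method))
  dt[, `:=`(entity_id = entity_id, entity_kind = entity_kind,
            event_kind = event_kind,
            event_level = if (event_kind == "outcome") NA_integer_
                          else as.integer(event_level),
            b = n_exp - a, c = n_event - a)]
  dt[, d := n_total - n_exp - c]
  dt[, n_event := NULL]
  setcolorder(dt, c("entity_id", "entity_kind", "event_id", "event_kind",
                    "event_level", "a", "b", "c", "d"))
  .rank_profile(.finish_signals(dt, filter, q_method))[]
}

#' Screen all entities of a kind against all events of a kind
#'
#' Forms every (entity, event) pair where the entity is linked to at least
#' `min_entity_support` cases and the event is observed at least once in
#' the corpus (with the entity or not), computes counts, PRR, Fisher p and
#' q-values over the whole screen, and attaches a summary of how many
#' associations pass each flag.
#'
#' @inheritParams profile_entity
#' @return A `data.table` of signal records with a `"summary"` attribute
#'   (list of counts and fractions per flag).
#' @export
screen_all <- function(corpus, entity_kind, event_kind, event_level = 4L,
                       hierarchy = NULL, filter = signal_filter(),
                       q_method = "BH") {
  entity_kind <- match.arg(entity_kind, .ENTITY_KINDS)
  col <- switch(entity_kind,
                drug = "drug_ids", target = "target_ids",
                enzyme = "enzyme_ids", carrier = "carrier_ids",
                transporter = "transporter_ids", pathway = "pathway_ids",
                atc_class = "atc_classes")
  if (!col %in% names(corpus))
    stop(sprintf("corpus lacks '%s'; run annotate_cases()", col), call. = FALSE)
  vals <- corpus[[col]]
  n <- lengths(vals)
  expo <- data.table(idx = rep(seq_along(vals), n),
                     entity_id = unlist(vals, use.names = FALSE))
  expo <- unique(expo)
  n_total <- nrow(corpus)
  empty <- data.table(entity_id = character(0), entity_kind = character(0),
                      event_id = character(0), event_kind = character(0),
                      event_level = integer(0), a = numeric(0), b = numeric(0),
                      c = numeric(0), d = numeric(0))
  if (!nrow(expo)) {
    out <- .finish_signals(empty, filter, q_method)
    setattr(out, "summary", .screen_summary(out))
    return(out[])
  }
  support <- expo[, .(n_entity = .N), by = entity_id]
  support <- support[n_entity >= filter$min_entity_support]
  expo <- expo[entity_id %in% support$entity_id]
  ev <- .event_cases(corpus, hierarchy, event_kind, event_level)
  totals <- ev[, .(n_event = .N), by = event_id]
  if (!nrow(expo) || !nrow(totals)) {
    out <- .finish_signals(empty, filter, q_method)
    setattr(out, "summary", .screen_summary(out))
    return(out[])
  }
  pairs <- merge(expo, ev, by = "idx", allow.cartesian = TRUE)[
    , .(a = .N), by = .(entity_id, event_id)]
  grid <- CJ(entity_id = support$entity_id, event_id = totals$event_id)
  dt <- merge(grid, pairs, by = c("entity_id", "event_id"), all.x = TRUE)
  dt[is.na(a), a := 0]
  dt <- merge(dt, support, by = "entity_id")
  dt <- merge(dt, totals, by = "event_id")
  dt[, `:=`(b = n_entity - a, c = n_event - a)]
  dt[, d := n_total - n_entity - c]
  dt[, `:=`(n_entity = NULL, n_event = NULL,
            entity_kind = entity_kind, event_kind = event_kind,
            event_level = if (event_kind == "outcome") NA_integer_
                          else as.integer(event_level))]
  setcolorder(dt, c("entity_id", "entity_kind", "event_id", "event_kind",
                    "event_level", "a", "b", "c", "d"))
  out <- .finish_signals(dt, filter, q_method)
  setorderv(out, c("entity_id", "event_id"))
  setattr(out, "summary", .screen_summary(out))
  out[]
}

.screen_summary <- function(dt) {
  n <- nrow(dt)
  list(n_pairs = n,
       n_supported = sum(dt$supported), n_strong = sum(dt$strong),
       n_significant = sum(dt$significant), n_flagged = sum(dt$flagged),
       frac_supported = if (n) mean(dt$supported) else NA_real_,
       frac_strong = if (n) mean(dt$strong) else NA_real_,
       frac_significant = if (n) mean(dt$significant) else NA_real_,
       frac_flagged = if (n) mean(dt$flagged) else NA_real_)
}

#' Screen summary
#'
#' @param screen A table returned by [screen_all()].
#' @return The list of per-flag counts and fractions.
#' @export
screen_summary <- function(screen) attr(screen, "summary", exact = TRUE)

#' Mechanism-stratified profiles of a target
#'
#' Splits target-exposed cases by the pharmacologic action of the drugs
#' engaging the target.  Cases engaged only by agonists form the agonist
#' partition, only by antagonists the antagonist partition; cases carrying
#' both actions (conflicts), or only action "unknown", are excluded from
#' both sides.  Each side's profile contrasts its exposed cases against the
#' never-exposed cases, so each side's N equals its partition size.
#'
#' @inheritParams profile_entity
#' @param target_id Protein id.
#' @return List with elements `agonist` and `antagonist` (signal tables;
#'   empty with a warning when one action is absent).
#' @export
mechanism_profiles <- function(corpus, target_id, event_kind = "reaction",
                               event_level = 4L, hierarchy = NULL,
                               filter = signal_filter(), q_method = "BH") {
  texp <- .exposure_vec(corpus, "target", target_id)
  ag <- vapply(corpus$target_actions,
               function(t) paste0(target_id, ":agonist") %in% t, logical(1))
  an <- vapply(corpus$target_actions,
               function(t) paste0(target_id, ":antagonist") %in% t, logical(1))
  conflict <- ag & an
  one_side <- function(mine, other) {
    keep_exposed <- mine & !other & !conflict
    if (!any(keep_exposed)) {
      warning(sprintf("target %s has no %s-only cases; empty profile",
                      target_id,
                      if (identical(mine, ag)) "agonist" else "antagonist"))
      return(.profile_from_exposure(corpus[0], logical(0), "target",
                                    target_id, event_kind, event_level,
                                    hierarchy, filter, q_method))
    }
    keep <- keep_exposed | !texp
    sub <- corpus[keep]
    setattr(sub, "class", class(corpus))
    .profile_from_exposure(sub, keep_exposed[keep], "target", target_id,
                           event_kind, event_level, hierarchy, filter,
                           q_method)
  }
  list(agonist = one_side(ag, an), antagonist = one_side(an, ag))
}
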