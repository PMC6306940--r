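# Contrast of direct target-level signals against indirect drug-mediated
# signals for known target-effect pairs.

#' Construct a benchmark pair table
#'
#' Each known protein-effect pair names one or two effect-term synonyms
#' with their hierarchy levels (a second synonym covers spelling variants
#' or a broader class used when the specific term is scantly reported).
#'
#' @param pairs A table with columns `protein_id`, `effect_term_1`,
#'   `level_1`, and optionally `effect_term_2`, `level_2` (empty/NA when
#'   absent).
#' @return A validated `benchmark_pairs` `data.table`.
#' @export
benchmark_pairs <- function(pairs) {
  pairs <- as.data.table(pairs)
  .assert_cols(pairs, c("protein_id", "effect_term_1", "level_1"),
               "benchmark pairs")
  if (!"effect_term_2" %in% names(pairs))
    pairs[, `:=`(effect_term_2 = NA_character_, level_2 = NA_integer_)]
  pairs[, `:=`(protein_id = as.character(protein_id),
               effect_term_1 = as.character(effect_term_1),
               level_1 = as.integer(level_1),
               effect_term_2 = {
                 e <- as.character(effect_term_2)
                 fifelse(is.na(e) | !nzchar(e), NA_character_, e)
               },
               level_2 = as.integer(level_2))]
  if (any(!nzchar(pairs$effect_term_1) | is.na(pairs$effect_term_1)))
    stop("every benchmark pair needs at least one effect term", call. = FALSE)
  setattr(pairs, "class", unique(c("benchmark_pairs", class(pairs))))
  pairs[]
}

#' Read a benchmark pair file
#'
#' TSV with columns `protein_id`, `effect_term_1`, `level_1` and optional
#' `effect_term_2`, `level_2`.
#'
#' @param path File path.
#' @return A `benchmark_pairs` table.
#' @export
read_benchmark_pairs <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  benchmark_pairs(fread(path, sep = "\t", na.strings = c("", "NA")))
}

# choose the effect synonym to evaluate: most specific first, falling back
# to a broader synonym when the specific one is scantly observed
.choose_effect_term <- function(corpus, hierarchy, pair, min_cooccurrence) {
  cand <- data.table(term = c(pair$effect_term_1, pair$effect_term_2),
                     level = c(pair$level_1, pair$level_2))
  cand <- cand[!is.na(term)]
  setorder(cand, -level)
  cand[, count := vapply(seq_len(.N), function(i) {
    ev <- .event_cases(corpus, hierarchy, "reaction", cand$level[i])
    sum(ev$event_id == cand$term[i])
  }, numeric(1))]
  if (all(cand$count == 0)) return(NULL)
  ok <- cand[count >= min_cooccurrence]
  if (nrow(ok)) ok[1] else cand[which.max(count)]
}

#' Direct target-level signal for a benchmark pair
#'
#' Case-level disproportionality of the protein against the pair's effect:
#' the most specific synonym is used unless it co-occurs in fewer than
#' `min_cooccurrence` cases, in which case the broader synonym takes over.
#' Proteins engaged by no mapped drug in the corpus are recorded as
#' unevaluable rather than erroring.
#'
#' @param corpus An annotated corpus.
#' @param pair One row of a [benchmark_pairs()] table.
#' @param hierarchy The [phenotype_hierarchy()].
#' @param filter A [signal_filter()].
#' @return A one-row `data.table` (evaluable flag, chosen term/level,
#'   counts, prr, p) or an unevaluable stub.
#' @export
direct_signal <- function(corpus, pair, hierarchy, filter = signal_filter()) {
  stub <- data.table(protein_id = pair$protein_id, evaluable = FALSE,
                     term = NA_character_, level = NA_integer_,
                     support = 0, a = NA_real_, b = NA_real_, c = NA_real_,
                     d = NA_real_, prr = NA_real_, p = NA_real_)
  exposed <- .exposure_vec(corpus, "target", pair$protein_id)
  support <- sum(exposed)
  if (support == 0L) return(stub)
  chosen <- .choose_effect_term(corpus, hierarchy, pair,
                                filter$min_cooccurrence)
  if (is.null(chosen)) { stub$support <- support; return(stub) }
  tab <- build_contingency(corpus, "target", pair$protein_id, "reaction",
                           chosen$term, chosen$level, hierarchy)
  data.table(protein_id = pair$protein_id, evaluable = TRUE,
             term = chosen$term, level = chosen$level, support = support,
             a = tab$a, b = tab$b, c = tab$c, d = tab$d,
             prr = prr(tab, permissive = TRUE),
             p = fisher_exact(tab))
}

#' Indirect drug-mediated signal for a benchmark pair
#'
#' Drug-level 2x2 over the drugs observed in the corpus: `a` = drugs
#' targeting the protein and co-reported (in at least one case) with the
#' effect, `b` = targeting but never co-reported, `c` = co-reported but not
#' targeting, `d` = neither.  Also reports the maximum, mean and minimum
#' case-level drug-effect PRR among the targeting drugs, quantifying the
#' spread the drug-level aggregation hides.
#'
#' @inheritParams direct_signal
#' @param links A [target_links()] table.
#' @return A one-row `data.table` (drug-level counts, prr, p, PRR spread).
#' @export
indirect_signal <- function(corpus, pair, hierarchy, links,
                            filter = signal_filter()) {
  observed <- sort(unique(unlist(corpus$drug_ids, use.names = FALSE)))
  targeting <- intersect(observed,
                         links[role == "target" &
                                 protein_id == pair$protein_id, drug_id])
  if (!length(targeting))
    stop(sprintf("no observed drug targets protein %s", pair$protein_id),
         call. = FALSE)
  chosen <- .choose_effect_term(corpus, hierarchy, pair,
                                filter$min_cooccurrence)
  if (is.null(chosen))
    return(data.table(protein_id = pair$protein_id, evaluable = FALSE,
                      term = NA_character_, level = NA_integer_,
                      a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
                      prr = NA_real_, p = NA_real_, prr_max = NA_real_,
                      prr_mean = NA_real_, prr_min = NA_real_))
  ev <- .event_cases(corpus, hierarchy, "reaction", chosen$level)
  has_event <- rep(FALSE, nrow(corpus))
  has_event[ev$idx[ev$event_id == chosen$term]] <- TRUE
  # co-reporting determined in one pass over the long (case, drug) table
  long <- data.table(idx = rep(seq_len(nrow(corpus)),
                               lengths(corpus$drug_ids)),
                     drug_id = unlist(corpus$drug_ids, use.names = FALSE))
  co_drugs <- unique(long[has_event[idx], drug_id])
  is_t <- observed %in% targeting
  is_c <- observed %in% co_drugs
  tab <- contingency_table(sum(is_t & is_c), sum(is_t & !is_c),
                           sum(!is_t & is_c), sum(!is_t & !is_c))
  per_drug <- vapply(targeting, function(d) {
    dexp <- rep(FALSE, nrow(corpus))
    dexp[long$idx[long$drug_id == d]] <- TRUE
    .prr_vec(sum(dexp & has_event), sum(dexp & !has_event),
             sum(!dexp & has_event), sum(!dexp & !has_event))
  }, numeric(1))
  data.table(protein_id = pair$protein_id, evaluable = TRUE,
             term = chosen$term, level = chosen$level,
             a = tab$a, b = tab$b, c = tab$c, d = tab$d,
             prr = prr(tab, permissive = TRUE), p = fisher_exact(tab),
             prr_max = max(per_drug), prr_mean = mean(per_drug),
             prr_min = min(per_drug))
}

#' Recapitulation of benchmark pairs by each method
#'
#' Evaluates every pair with both the direct (case-level, target-centric)
#' and the indirect (drug-level) method, computes q-values per method over
#' the evaluable pairs, applies the same flag thresholds to both
#' (co-occurrence, PRR, q), and reports per-pair flags, per-method totals
#' and their ratio.
#'
#' @inheritParams indirect_signal
#' @param pairs A [benchmark_pairs()] table.
#' @return A list: `per_pair` table (direct/indirect counts, PRR, p, q,
#'   flags), `n_direct`, `n_indirect`, `ratio` (direct/indirect totals;
#'   `NA` when the indirect total is zero).
#' @export
recapitulation <- function(corpus, pairs, hierarchy, links,
                           filter = signal_filter()) {
  stopifnot(inherits(pairs, "benchmark_pairs"))
  if (!nrow(pairs))
    return(list(per_pair = data.table(), n_direct = 0L, n_indirect = 0L,
                ratio = NA_real_))
  dir_l <- lapply(seq_len(nrow(pairs)), function(i)
    direct_signal(corpus, pairs[i], hierarchy, filter))
  ind_l <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i]
    obs <- links[role == "target" & protein_id == p$protein_id, drug_id]
    if (!length(intersect(obs, unique(unlist(corpus$drug_ids)))))
      data.table(protein_id = p$protein_id, evaluable = FALSE,
                 term = NA_character_, level = NA_integer_, a = NA_real_,
                 b = NA_real_, c = NA_real_, d = NA_real_, prr = NA_real_,
                 p = NA_real_, prr_max = NA_real_, prr_mean = NA_real_,
                 prr_min = NA_real_)
    else indirect_signal(corpus, p, hierarchy, links, filter)
  })
  direct <- rbindlist(dir_l)
  indirect <- rbindlist(ind_l)
  flag <- function(dt) {
    dt[, q := NA_real_]
    ev <- which(dt$evaluable & !is.na(dt$p))
    if (length(ev)) dt$q[ev] <- qvalues(dt$p[ev])
    dt[, flagged := evaluable & !is.na(a) & a >= filter$min_cooccurrence &
         !is.na(prr) & prr >= filter$prr_threshold &
         !is.na(q) & q < filter$q_threshold]
    dt
  }
  direct <- flag(direct)
  indirect <- flag(indirect)
  setnames(direct, setdiff(names(direct), "protein_id"),
           paste0("direct_", setdiff(names(direct), "protein_id")))
  setnames(indirect, setdiff(names(indirect), "protein_id"),
           paste0("indirect_", setdiff(names(indirect), "protein_id")))
  per_pair <- cbind(direct, indirect[, !"protein_id"])
  n_d <- sum(per_pair$direct_flagged)
  n_i <- sum(per_pair$indirect_flagged)
  list(per_pair = per_pair, n_direct = n_d, n_indirect = n_i,
       ratio = if (n_i > 0) n_d / n_i else NA_real_)
}
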