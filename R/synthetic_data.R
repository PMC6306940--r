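# Generator of a complete toy world (phenotype hierarchy, drug dictionary,
# drug-protein links, protein annotations) and of FAERS-like case corpora
# with planted target-reaction effects, name corruption and blacklist
# noise.  Every downstream stage is testable against the recorded ground
# truth, without any external download.

.ATC_CLASSES <- c("C07AA", "C07AB", "C07AG",   # beta-blocker-like classes
                  "L01XE", "N02BA", "J01CA", "A10BA", "R03AC")
.BLACKLIST_TOKENS <- c("UNKNOWN", "UNK")

#' Configuration of the synthetic world
#'
#' Defaults state the simulated world used throughout: 50,000 cases over 60
#' drugs and 80 proteins, 64 specific reaction terms with a 1% per-case
#' background reporting probability, 10 planted protein-reaction effects at
#' risk multiplier 5, 20% of mentions corrupted by at most 2 character
#' edits, 2% blacklist mentions, reports dated 2000-2016.
#'
#' @param seed Integer seed; the whole dataset is a pure function of the
#'   configuration.
#' @param n_cases Number of case reports.
#' @param n_drugs,n_proteins,n_reaction_leaves,n_indication_leaves World
#'   sizes.
#' @param background_reaction_prob Per-(case, leaf) background probability.
#' @param n_planted,planted_multiplier Number of planted protein-reaction
#'   pairs and their shared risk multiplier (>= 1); exposure to any drug
#'   targeting a planted protein raises that reaction's probability to
#'   `min(1, multiplier * background)`.
#' @param planted_signals Optional explicit `data.frame(protein_id,
#'   term_id, multiplier)` overriding `n_planted`/`planted_multiplier`.
#' @param typo_prob,max_edits Mention corruption: probability that a
#'   mention is misspelled, and the maximum number of character edits
#'   (0-3; at most 2 keeps corrupted names unambiguous when dictionary
#'   names are >= 5 edits apart).
#' @param lump_prob Probability that two of a case's drugs are reported as
#'   one "A + B" lumped mention.
#' @param blacklist_mention_prob Probability of injecting an irrelevant
#'   token ("UNKNOWN"/"UNK") as an extra mention.
#' @param non_target_role_frac Fraction of proteins additionally listed as
#'   metabolizing enzymes or transporters of some drug (these fail the
#'   clean-target filter).
#' @param protective_outcome Optional list `(atc_prefix, outcome,
#'   rate_exposed, rate_unexposed)`: cases exposed to a drug in the ATC
#'   prefix carry the outcome at `rate_exposed`, others at
#'   `rate_unexposed`.
#' @param undated_prob Fraction of cases without a report date.
#' @param date_range Character or Date vector of length 2.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(seed,
                             n_cases = 50000L,
                             n_drugs = 60L,
                             n_proteins = 80L,
                             n_reaction_leaves = 64L,
                             n_indication_leaves = 12L,
                             background_reaction_prob = 0.01,
                             n_planted = 10L,
                             planted_multiplier = 5,
                             planted_signals = NULL,
                             typo_prob = 0.2,
                             max_edits = 2L,
                             lump_prob = 0.02,
                             blacklist_mention_prob = 0.02,
                             non_target_role_frac = 0.3,
                             protective_outcome = NULL,
                             undated_prob = 0.02,
                             date_range = c("2000-01-01", "2016-12-31")) {
  cfg <- list(seed = as.integer(seed), n_cases = as.integer(n_cases),
              n_drugs = as.integer(n_drugs),
              n_proteins = as.integer(n_proteins),
              n_reaction_leaves = as.integer(n_reaction_leaves),
              n_indication_leaves = as.integer(n_indication_leaves),
              background_reaction_prob = background_reaction_prob,
              n_planted = as.integer(n_planted),
              planted_multiplier = planted_multiplier,
              planted_signals = planted_signals,
              typo_prob = typo_prob, max_edits = as.integer(max_edits),
              lump_prob = lump_prob,
              blacklist_mention_prob = blacklist_mention_prob,
              non_target_role_frac = non_target_role_frac,
              protective_outcome = protective_outcome,
              undated_prob = undated_prob,
              date_range = as.Date(date_range))
  probs <- c(cfg$background_reaction_prob, cfg$typo_prob, cfg$lump_prob,
             cfg$blacklist_mention_prob, cfg$non_target_role_frac,
             cfg$undated_prob)
  if (any(is.na(probs)) || any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (any(c(cfg$n_cases, cfg$n_drugs, cfg$n_proteins,
            cfg$n_reaction_leaves) < 1L))
    stop("world sizes must be >= 1", call. = FALSE)
  if (cfg$planted_multiplier < 1)
    stop("risk multiplier must be >= 1", call. = FALSE)
  if (cfg$max_edits < 0L || cfg$max_edits > 3L)
    stop("max_edits must be in 0..3", call. = FALSE)
  if (is.na(cfg$seed) || abs(cfg$seed) >= .Machine$integer.max)
    stop("seed must be a 32-bit integer", call. = FALSE)
  if (!is.null(cfg$protective_outcome)) {
    po <- cfg$protective_outcome
    stopifnot(all(c("atc_prefix", "outcome", "rate_exposed",
                    "rate_unexposed") %in% names(po)),
              po$outcome %in% .OUTCOME_CODES)
  }
  structure(cfg, class = "generator_config")
}

# pronounceable pseudo-names, pairwise Levenshtein distance >= min_sep
.gen_drug_names <- function(n, min_sep = 5L, n_syll = 5L) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
            "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  draw <- function(k) {
    vapply(seq_len(k), function(i)
      paste0(sample(cons, n_syll, TRUE), sample(vow, n_syll, TRUE),
             collapse = ""),
      character(1))
  }
  names <- draw(n)
  for (iter in 1:100) {
    d <- adist(names)
    diag(d) <- Inf
    bad <- unique(which(d < min_sep, arr.ind = TRUE)[, 1])
    if (!length(bad)) break
    names[bad] <- draw(length(bad))
  }
  if (anyDuplicated(names)) stop("could not separate generated drug names")
  names
}

.gen_tree <- function(n_leaves, prefix, name_stub) {
  fanout <- 4L
  n3 <- max(1L, ceiling(n_leaves / fanout))
  n2 <- max(1L, ceiling(n3 / fanout))
  n1 <- max(1L, ceiling(n2 / fanout))
  mk <- function(lvl, n) sprintf("%s%d_%03d", prefix, lvl, seq_len(n))
  l1 <- mk(1, n1); l2 <- mk(2, n2); l3 <- mk(3, n3); l4 <- mk(4, n_leaves)
  up <- function(i, n_par) ((i - 1L) %% n_par) + 1L
  rbind(
    data.table(term_id = l1, name = paste(name_stub, "class", seq_len(n1)),
               level = 1L, parent_id = NA_character_),
    data.table(term_id = l2,
               name = paste(name_stub, "group", seq_len(n2)),
               level = 2L, parent_id = l1[up(seq_len(n2), n1)]),
    data.table(term_id = l3,
               name = paste(name_stub, "subgroup", seq_len(n3)),
               level = 3L, parent_id = l2[up(seq_len(n3), n2)]),
    data.table(term_id = l4,
               name = paste(name_stub, "term", seq_len(n_leaves)),
               level = 4L, parent_id = l3[up(seq_len(n_leaves), n3)])
  )
}

#' Generate the synthetic world
#'
#' Deterministically (from `config$seed`) builds the 4-level phenotype
#' hierarchy (separate reaction and indication subtrees), the drug synonym
#' dictionary (one canonical name plus one brand synonym per drug, all
#' names pairwise >= 5 edits apart so that bounded fuzzy matching is
#' unambiguous under <= 2-edit corruption), drug-protein links (1-3 targets
#' per drug with pharmacologic actions; a configurable fraction of proteins
#' additionally carries enzyme/transporter roles), protein annotations with
#' toy pathways, ATC class assignments, and the planted protein-reaction
#' effect table.
#'
#' @param config A [generator_config()].
#' @return A list of class `synthetic_world`: `hierarchy`, `dictionary`,
#'   `links`, `annotations`, `planted`, `blacklist`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  hierarchy <- phenotype_hierarchy(rbind(
    .gen_tree(config$n_reaction_leaves, "R", "reaction"),
    .gen_tree(config$n_indication_leaves, "I", "indication")))

  names <- .gen_drug_names(2L * config$n_drugs)
  canon <- names[seq_len(config$n_drugs)]
  brand <- names[config$n_drugs + seq_len(config$n_drugs)]
  drug_ids <- sprintf("D%03d", seq_len(config$n_drugs))
  atc <- paste0(.ATC_CLASSES[((seq_len(config$n_drugs) - 1L) %%
                                length(.ATC_CLASSES)) + 1L],
                sprintf("%02d", seq_len(config$n_drugs)))
  dict_tab <- rbind(
    data.table(drug_id = drug_ids, canonical_name = canon, synonym = canon,
               atc_codes = atc),
    data.table(drug_id = drug_ids, canonical_name = canon, synonym = brand,
               atc_codes = atc))
  dictionary <- drug_dictionary(dict_tab)

  protein_ids <- sprintf("P%03d", seq_len(config$n_proteins))
  n_targets <- sample(1:3, config$n_drugs, replace = TRUE)
  link_list <- lapply(seq_len(config$n_drugs), function(i) {
    prot <- sample(protein_ids, n_targets[i])
    data.table(drug_id = drug_ids[i], protein_id = prot, role = "target",
               action = sample(c("agonist", "antagonist", "unknown"),
                               length(prot), TRUE,
                               prob = c(0.3, 0.4, 0.3)))
  })
  links <- rbindlist(link_list)
  n_dirty <- round(config$non_target_role_frac * config$n_proteins)
  if (n_dirty > 0L) {
    dirty <- sample(protein_ids, n_dirty)
    extra <- data.table(
      drug_id = sample(drug_ids, n_dirty, replace = TRUE),
      protein_id = dirty,
      role = sample(c("enzyme", "transporter", "carrier"), n_dirty, TRUE,
                    prob = c(0.5, 0.3, 0.2)),
      action = "unknown")
    links <- rbind(links, extra)
  }
  links <- unique(links, by = c("drug_id", "protein_id", "role"))
  links <- target_links(links)

  n_pw <- max(1L, config$n_proteins %/% 8L)
  pw_ids <- sprintf("PW%02d", seq_len(n_pw))
  annotations <- protein_annotations(data.table(
    protein_id = protein_ids,
    gene_symbol = sprintf("GENE%03d", seq_len(config$n_proteins)),
    pathway_ids = lapply(seq_len(config$n_proteins), function(i)
      sample(pw_ids, min(length(pw_ids), sample(1:2, 1))))))

  if (!is.null(config$planted_signals)) {
    planted <- as.data.table(config$planted_signals)
    .assert_cols(planted, c("protein_id", "term_id", "multiplier"),
                 "planted_signals")
    if (!all(planted$protein_id %in% protein_ids) ||
        !all(planted$term_id %in% hierarchy$terms$term_id))
      stop("planted_signals reference unknown protein or term", call. = FALSE)
  } else {
    targeted <- unique(links[role == "target", protein_id])
    k <- min(config$n_planted, length(targeted), config$n_reaction_leaves)
    leaves <- hierarchy$terms[level == 4L & startsWith(term_id, "R"), term_id]
    planted <- data.table(protein_id = sample(targeted, k),
                          term_id = sample(leaves, k),
                          multiplier = config$planted_multiplier)
  }
  structure(list(hierarchy = hierarchy, dictionary = dictionary,
                 links = links, annotations = annotations, planted = planted,
                 blacklist = .BLACKLIST_TOKENS),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_world> %d drugs, %d proteins, %d terms, ",
                     "%d planted effects\n"),
              nrow(x$dictionary$concepts),
              length(unique(x$links$protein_id)), nrow(x$hierarchy$terms),
              nrow(x$planted)))
  invisible(x)
}

# apply k random character edits (substitute/insert/delete) to one name
.corrupt_name <- function(name, k) {
  letters_pool <- letters
  for (i in seq_len(k)) {
    ch <- strsplit(name, "")[[1]]
    op <- sample(c("sub", "ins", "del"), 1)
    if (op == "del" && length(ch) <= 2L) op <- "sub"
    if (op == "sub") {
      pos <- sample(length(ch), 1)
      ch[pos] <- sample(setdiff(letters_pool, ch[pos]), 1)
    } else if (op == "ins") {
      pos <- sample(length(ch) + 1L, 1)
      ch <- append(ch, sample(letters_pool, 1), after = pos - 1L)
    } else {
      pos <- sample(length(ch), 1)
      ch <- ch[-pos]
    }
    name <- paste(ch, collapse = "")
  }
  name
}

#' Generate a case corpus with planted effects
#'
#' Draws, per case: 1-3 drugs; background reactions per specific (level-4)
#' reaction term; elevated reaction probabilities for cases whose drugs
#' target a planted protein (`min(1, multiplier * background)`); 1-2
#' indications; the seven outcomes at fixed base rates (optionally
#' modulated by `protective_outcome`); a report date; and verbatim
#' mentions derived from dictionary synonyms with optional case changes,
#' typo corruption, drug lumping ("A + B") and blacklist token injection.
#'
#' @param config The [generator_config()] used for [generate_world()].
#' @param world The corresponding `synthetic_world`.
#' @return A list of class `synthetic_cases`: `corpus` (an [ae_corpus()])
#'   and `truth` (ground truth: `planted`, `mention_map` mapping each
#'   corrupted/lumped verbatim string to its intended drug(s), and
#'   `exposure` - the per-case true target-id sets).
#' @export
generate_cases <- function(config, world) {
  stopifnot(inherits(config, "generator_config"),
            inherits(world, "synthetic_world"))
  set.seed(config$seed + 1L)
  n <- config$n_cases
  leaves_r <- world$hierarchy$terms[level == 4L & startsWith(term_id, "R"),
                                    term_id]
  leaves_i <- world$hierarchy$terms[level == 4L & startsWith(term_id, "I"),
                                    term_id]
  drug_ids <- world$dictionary$concepts$drug_id
  canon <- setNames(world$dictionary$concepts$canonical_name, drug_ids)
  syn_by_drug <- split(world$dictionary$synonyms$synonym,
                       world$dictionary$synonyms$drug_id)
  tgt_lut <- .role_lut(world$links, "target")
  atc_lut <- setNames(world$dictionary$concepts$atc_codes, drug_ids)

  # drugs and true molecular exposure
  n_drugs_case <- sample(1:3, n, TRUE, prob = c(0.5, 0.3, 0.2))
  case_drugs <- lapply(n_drugs_case, function(k) sample(drug_ids, k))
  exposure <- lapply(case_drugs, function(ds)
    .sunion(unlist(tgt_lut[ds], use.names = FALSE)))

  # reactions: background Bernoulli per leaf, boosted for planted exposures
  p0 <- config$background_reaction_prob
  mat <- matrix(runif(n * length(leaves_r)) < p0, nrow = n)
  colnames(mat) <- leaves_r
  for (j in seq_len(nrow(world$planted))) {
    prot <- world$planted$protein_id[j]
    term <- world$planted$term_id[j]
    mult <- world$planted$multiplier[j]
    rows <- which(vapply(exposure, function(e) prot %in% e, logical(1)))
    if (length(rows))
      mat[rows, term] <- runif(length(rows)) < min(1, mult * p0)
  }
  hit <- which(mat, arr.ind = TRUE)
  reactions <- rep(list(character(0)), n)
  if (nrow(hit)) {
    by_row <- split(leaves_r[hit[, 2]], hit[, 1])
    reactions[as.integer(names(by_row))] <- lapply(by_row, sort)
  }

  indications <- lapply(sample(1:2, n, TRUE, prob = c(0.7, 0.3)),
                        function(k) sample(leaves_i, k))

  # outcomes at fixed base rates; optional protective modulation
  base_rates <- c(DE = 0.05, LT = 0.02, HO = 0.15, DS = 0.02, CA = 0.01,
                  RI = 0.01, OT = 0.30)
  omat <- matrix(runif(n * 7) < rep(base_rates, each = n), nrow = n)
  colnames(omat) <- names(base_rates)
  if (!is.null(config$protective_outcome)) {
    po <- config$protective_outcome
    atc_exposed <- vapply(case_drugs, function(ds) {
      codes <- unlist(atc_lut[ds], use.names = FALSE)
      length(codes) > 0L && any(startsWith(codes, po$atc_prefix))
    }, logical(1))
    rate <- ifelse(atc_exposed, po$rate_exposed, po$rate_unexposed)
    omat[, po$outcome] <- runif(n) < rate
  }
  ohit <- which(omat, arr.ind = TRUE)
  outcomes <- rep(list(character(0)), n)
  if (nrow(ohit)) {
    by_row <- split(colnames(omat)[ohit[, 2]], ohit[, 1])
    outcomes[as.integer(names(by_row))] <- by_row
  }

  # dates
  span <- as.integer(config$date_range[2] - config$date_range[1])
  dates <- config$date_range[1] + sample(0:span, n, TRUE)
  dates[runif(n) < config$undated_prob] <- NA

  # verbatim mentions: synonym choice, case style, lumping, typos,
  # blacklist injection
  mention_rows <- vector("list", n)
  mentions <- vector("list", n)
  for (i in seq_len(n)) {
    ds <- case_drugs[[i]]
    raw <- vapply(ds, function(d) {
      syns <- syn_by_drug[[d]]
      s <- if (length(syns) > 1L && runif(1) < 0.3) syns[2] else canon[[d]]
      if (runif(1) < config$typo_prob && config$max_edits > 0L)
        s <- .corrupt_name(s, sample(config$max_edits, 1))
      if (runif(1) < 0.5) toupper(s) else s
    }, character(1))
    intended <- as.list(ds)
    if (length(ds) >= 2L && runif(1) < config$lump_prob) {
      raw <- c(paste(raw[1], "+", raw[2]), raw[-(1:2)])
      intended <- c(list(ds[1:2]), intended[-(1:2)])
    }
    if (runif(1) < config$blacklist_mention_prob) {
      raw <- c(raw, sample(.BLACKLIST_TOKENS, 1))
      intended <- c(intended, list(character(0)))
    }
    mentions[[i]] <- raw
    mention_rows[[i]] <- data.table(
      case_idx = i,
      verbatim = rep(raw, lengths(intended) + (lengths(intended) == 0L)),
      drug_id = {
        v <- unlist(intended, use.names = FALSE)
        out <- character(sum(lengths(intended) + (lengths(intended) == 0L)))
        k <- 1L
        for (m in seq_along(intended)) {
          len <- length(intended[[m]])
          if (len == 0L) { out[k] <- NA_character_; k <- k + 1L }
          else { out[k:(k + len - 1L)] <- intended[[m]]; k <- k + len }
        }
        out
      })
  }
  mention_map <- rbindlist(mention_rows)
  case_ids <- sprintf("C%07d", seq_len(n))
  mention_map[, case_id := case_ids[case_idx]]
  mention_map[, case_idx := NULL]

  corpus <- ae_corpus(case_id = case_ids, report_date = dates,
                      drug_mentions = mentions, indications = indications,
                      reactions = reactions, outcomes = outcomes)
  truth <- list(planted = copy(world$planted),
                case_drugs = setNames(case_drugs, case_ids),
                mention_map = mention_map[],
                exposure = setNames(exposure, case_ids))
  structure(list(corpus = corpus, truth = truth), class = "synthetic_cases")
}

#' Generate world and cases in one call
#'
#' @param config A [generator_config()].
#' @return List with `world`, `corpus`, `truth`.
#' @export
simulate_dataset <- function(config) {
  world <- generate_world(config)
  cases <- generate_cases(config, world)
  list(world = world, corpus = cases$corpus, truth = cases$truth)
}

#' Write a synthetic dataset to a directory
#'
#' Emits every table in the package's delimited formats plus a ground-truth
#' file (`planted.tsv`, `mention_map.tsv`).
#'
#' @param dataset Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @param dialect Case-table dialect, see [write_cases()].
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, dialect = "tab") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- dataset$world
  write_cases(dataset$corpus, file.path(dir, "cases.tsv"), dialect)
  write_hierarchy(w$hierarchy, file.path(dir, "hierarchy.tsv"))
  write_dictionary(w$dictionary, file.path(dir, "dictionary.tsv"))
  write_links(w$links, file.path(dir, "links.tsv"))
  write_annotations(w$annotations, file.path(dir, "annotations.tsv"))
  writeLines(w$blacklist, file.path(dir, "blacklist.txt"))
  fwrite(w$planted, file.path(dir, "planted.tsv"), sep = "\t")
  fwrite(dataset$truth$mention_map, file.path(dir, "mention_map.tsv"),
         sep = "\t")
  invisible(dir)
}
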