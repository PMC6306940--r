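# Constructed benchmark world: each of k targets has n_drugs_per drugs;
# only the first `carriers` of them confer the target's effect reaction at
# p_hit (the rest at the p_bg background).  Used by the benchmark unit
# tests and the direct-vs-indirect acceptance criterion.
make_bench_world <- function(k = 4, n_drugs_per = 4, carriers = 1,
                             n_cases = 3000, p_hit = 0.3, p_bg = 0.01,
                             seed = 1) {
  set.seed(seed)
  drug_ids <- sprintf("B%02d_%d", rep(1:k, each = n_drugs_per),
                      rep(1:n_drugs_per, k))
  names <- sprintf("bdrugname%02d%s", seq_along(drug_ids),
                   strrep(letters[(seq_along(drug_ids) %% 26) + 1], 3))
  dict <- drug_dictionary(data.frame(
    drug_id = drug_ids, canonical_name = names, synonym = names,
    atc_codes = ""))
  links <- target_links(data.frame(
    drug_id = drug_ids,
    protein_id = sprintf("TB%02d", rep(1:k, each = n_drugs_per)),
    role = "target", action = "antagonist"))
  terms <- rbind(
    data.frame(term_id = "ROOT", name = "root", level = 1, parent_id = NA),
    data.frame(term_id = "L2", name = "l2", level = 2, parent_id = "ROOT"),
    data.frame(term_id = "L3", name = "l3", level = 3, parent_id = "L2"),
    data.frame(term_id = sprintf("EFF%02d", 1:k),
               name = sprintf("effect %d", 1:k), level = 4,
               parent_id = "L3"))
  h <- phenotype_hierarchy(terms)
  case_drug <- sample(drug_ids, n_cases, TRUE)
  is_carrier <- as.integer(sub("^B\\d+_", "", case_drug)) <= carriers
  tgt_idx <- as.integer(sub("^B(\\d+)_\\d+$", "\\1", case_drug))
  reactions <- lapply(seq_len(n_cases), function(i) {
    out <- sprintf("EFF%02d", which(runif(k) < p_bg))
    p <- if (is_carrier[i]) p_hit else p_bg
    eff <- sprintf("EFF%02d", tgt_idx[i])
    if (runif(1) < p) out <- union(out, eff)
    out
  })
  corpus <- ae_corpus(case_id = sprintf("K%05d", 1:n_cases),
                      report_date = as.Date("2012-01-01"),
                      drug_mentions = as.list(names[match(case_drug,
                                                          drug_ids)]),
                      indications = rep(list(character(0)), n_cases),
                      reactions = reactions,
                      outcomes = rep(list(character(0)), n_cases))
  ann <- annotate_cases(map_corpus(corpus, dict), links, NULL, dict)
  pairs <- benchmark_pairs(data.frame(
    protein_id = sprintf("TB%02d", 1:k),
    effect_term_1 = sprintf("EFF%02d", 1:k), level_1 = 4))
  list(ann = ann, links = links, hierarchy = h, pairs = pairs)
}
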