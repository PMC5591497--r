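# synthetic validation cohort: 8 subjects x 6 genes with mixed heterozygous /
# homozygous / absent / copy-number-variant truth, the desk analogue of a
# published-style concordance table.  Cell codes:
#   neg2      two reference copies                 -> -/-
#   het       reference + novel                    -> +/+
#   hom       two novel copies                     -> +/+ (homozygous-like)
#   cnv_nov3  reference + synthetic known + novel  -> +/+ with CNV flag
#   cnv_neg3  three distinct known alleles         -> -/- with CNV flag
#   cnv_neg4  four copies, three distinct known    -> -/- with CNV flag
#   del       zero copies                          -> no call, N.D., deletion flag

cohort_candidates <- function() {
  c("IGHV1-8"  = "IGHV1-8*02 (G234T)",
    "IGHV1-69" = "IGHV1-69*01 (G163A)",
    "IGHV3-30" = "IGHV3-30*02 (T201C)",
    "IGHV4-31" = "IGHV4-31*02 (C198T)",
    "IGHV4-59" = "IGHV4-59*01 (T109C)",
    "IGHV4-61" = "IGHV4-61*01 (C93T_C136G_A138C)")
}

cohort_truth <- function() {
  genes <- names(cohort_candidates())
  layout <- rbind(
    c("het",  "cnv_nov3", "neg2",     "neg2", "het",  "neg2"),
    c("neg2", "neg2",     "cnv_neg3", "del",  "hom",  "het"),
    c("hom",  "het",      "het",      "het",  "neg2", "del"),
    c("neg2", "cnv_neg4", "cnv_nov3", "neg2", "neg2", "hom"),
    c("het",  "neg2",     "neg2",     "del",  "het",  "neg2"),
    c("neg2", "cnv_neg3", "cnv_nov3", "neg2", "neg2", "del"),
    c("het",  "hom",      "neg2",     "het",  "neg2", "neg2"),
    c("neg2", "neg2",     "cnv_neg4", "neg2", "hom",  "het")
  )
  tidyr::expand_grid(subject = sprintf("S%d", 1:8), gene = genes) |>
    dplyr::mutate(type = as.vector(t(layout))[
      (match(subject, sprintf("S%d", 1:8)) - 1L) * length(genes) +
        match(gene, genes)])
}

cohort_genotype_spec <- function(truth_rows) {
  cands <- cohort_candidates()
  rows <- lapply(seq_len(nrow(truth_rows)), function(r) {
    gene <- truth_rows$gene[r]
    type <- truth_rows$type[r]
    syn90 <- paste0(gene, "*90")
    syn91 <- paste0(gene, "*91")
    cand <- cands[[gene]]
    base <- parse_novel_name(cand)$base
    switch(type,
      neg2 = tibble::tibble(gene = gene, copies = 2L, alleles = list(NULL),
                            novel = NA_character_, novel_copies = 1L),
      het = tibble::tibble(gene = gene, copies = 2L, alleles = list(NULL),
                           novel = cand, novel_copies = 1L),
      hom = tibble::tibble(gene = gene, copies = 2L, alleles = list(NULL),
                           novel = cand, novel_copies = 2L),
      cnv_nov3 = tibble::tibble(gene = gene, copies = 3L,
                                alleles = list(c(base, syn90, base)),
                                novel = cand, novel_copies = 1L),
      cnv_neg3 = tibble::tibble(gene = gene, copies = 3L,
                                alleles = list(c(base, syn90, syn91)),
                                novel = NA_character_, novel_copies = 1L),
      cnv_neg4 = tibble::tibble(gene = gene, copies = 4L,
                                alleles = list(c(base, base, syn90, syn91)),
                                novel = NA_character_, novel_copies = 1L),
      del = tibble::tibble(gene = gene, copies = 0L, alleles = list(NULL),
                           novel = NA_character_, novel_copies = 1L)
    )
  })
  dplyr::bind_rows(rows)
}

cohort_expectation <- function(type) {
  list(
    predicted = type %in% c("het", "hom", "cnv_nov3"),
    val_status = dplyr::case_match(type,
      c("het", "hom", "cnv_nov3") ~ "positive",
      c("neg2", "cnv_neg3", "cnv_neg4") ~ "negative",
      "del" ~ "failed"),
    cnv = type %in% c("cnv_nov3", "cnv_neg3", "cnv_neg4"),
    deletion = type == "del"
  )
}

# run the full pipeline for one seed; returns one row per subject x gene with
# observed and expected statuses and flags
run_cohort <- function(seed, db = example_germline_db(),
                       n_unique = 5000L, gdna_depth = 500L,
                       shm_rate = 0.005, seq_error_rate = 0.001) {
  truth <- cohort_truth()
  cands <- cohort_candidates()
  rep_params <- sim_params(n_unique = n_unique, shm_rate = shm_rate,
                           seq_error_rate = seq_error_rate,
                           gdna_depth = gdna_depth)
  out <- list()
  for (s in unique(truth$subject)) {
    rows <- truth[truth$subject == s, ]
    gt <- simulate_genotype(db, cohort_genotype_spec(rows))
    s_seed <- seed * 1000L + match(s, unique(truth$subject))
    reps <- simulate_igm_repertoire(gt, rep_params, seed = s_seed)
    asn <- batch_assign(reps, db)
    called <- call_novel_alleles(asn, db)$calls$novel_name
    for (g in rows$gene) {
      type <- rows$type[rows$gene == g]
      cand <- cands[[g]]
      gdna <- simulate_gdna_reads(gt, g, rep_params,
                                  seed = s_seed + 17L * match(g, rows$gene))
      val <- validate_candidate(gdna, db, cand, subject = s)
      filt <- filter_reads_to_allele_group(gdna, db, cand)
      cnv <- detect_cnv(filt, g, attr(filt, "db"))
      del <- detect_deletion(asn, filt, g, db)
      exp <- cohort_expectation(type)
      out[[length(out) + 1L]] <- tibble::tibble(
        subject = s, gene = g, type = type, candidate = cand,
        predicted = cand %in% called,
        val_status = val$status,
        novel_fraction = val$novel_fraction,
        cnv_flag = cnv$cnv_flag,
        deletion_flag = del$deletion_flag,
        exp_predicted = exp$predicted,
        exp_val_status = exp$val_status,
        exp_cnv = exp$cnv,
        exp_deletion = exp$deletion,
        extra_calls = sum(!called %in% cands)
      )
    }
  }
  dplyr::bind_rows(out)
}
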