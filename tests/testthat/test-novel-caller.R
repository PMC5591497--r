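db <- example_germline_db()

test_that("mismatch-ratio screen follows its definition", {
  # counts {0:90, 1:10} -> ratio 9, not triggered
  r <- compute_mismatch_ratios(
    batch_assign(planted_repertoire(db, "IGHV1-8*02", 210, 100, 10), db)
  )
  expect_equal(r$n[r$k == 0], 90L)
  expect_equal(r$ratio[r$k == 1], 9)
  expect_false(any(r$triggered))
  # counts {0:40, 1:60} -> ratio 2/3 < 2, triggered
  r2 <- compute_mismatch_ratios(
    batch_assign(planted_repertoire(db, "IGHV1-8*02", 210, 100, 60), db)
  )
  expect_equal(r2$ratio[r2$k == 1], 40 / 60)
  expect_equal(r2$k[r2$triggered], 1L)
  # homozygous-novel pattern: counts {0:0, 1:100} -> ratio 0, triggered
  r3 <- compute_mismatch_ratios(
    batch_assign(planted_repertoire(db, "IGHV1-8*02", 210, 100, 100), db)
  )
  expect_equal(r3$n[r3$k == 0], 0L)
  expect_equal(r3$ratio[r3$k == 1], 0)
  expect_true(r3$triggered[r3$k == 1])

  mixed <- batch_assign(dplyr::bind_rows(
    planted_repertoire(db, "IGHV1-8*02", integer(), 10, 0),
    planted_repertoire(db, "IGHV4-59*01", integer(), 10, 0)
  ), db)
  expect_error(compute_mismatch_ratios(mixed), "mixed-allele group")
})

test_that("position profiles count per-position substitution fractions", {
  asn <- batch_assign(planted_repertoire(db, "IGHV1-8*02", 210, 100, 24,
                                         alt = "T"), db)
  prof <- build_position_profile(asn, db)
  expect_equal(attr(prof, "n_seqs"), 100L)
  expect_equal(nrow(prof), 1)
  expect_equal(prof$position, 210L)
  expect_equal(prof$alt, "T")
  expect_equal(prof$fraction, 0.24)
  # no mutations at all -> empty profile, full coverage
  clean <- batch_assign(planted_repertoire(db, "IGHV1-8*02", integer(), 60, 0), db)
  p0 <- build_position_profile(clean, db)
  expect_equal(nrow(p0), 0)
  expect_equal(attr(p0, "coverage"),
               rep(60L, nchar(db$sequence[match("IGHV1-8*02", db$name)])))
})

test_that("profile denominators use per-position coverage for truncated reads", {
  base <- db$sequence[match("IGHV1-8*02", db$name)]
  full <- planted_repertoire(db, "IGHV1-8*02", 210, 50, 10, alt = "T")
  truncated <- tibble::tibble(
    id = sprintf("t%03d", 1:50),
    sequence = substr(base, 101, nchar(base)),  # misses position 210? no: covers 101..end
    multiplicity = 1L
  )
  # 5'-truncated reads cover 101.. so they add to the denominator at 210
  asn <- batch_assign(dplyr::bind_rows(full, truncated), db)
  prof <- build_position_profile(asn, db)
  expect_equal(prof$coverage[prof$position == 210], 100L)
  expect_equal(prof$fraction[prof$position == 210], 0.10)
  # but not at positions before their start
  expect_equal(attr(prof, "coverage")[50], 50L)
})

test_that("candidate SNP thresholds behave at their boundaries", {
  p <- caller_params()
  # 24% share, clean position -> candidate
  asn <- batch_assign(planted_repertoire(db, "IGHV1-8*02", 210, 100, 24,
                                         alt = "T"), db)
  cand <- call_candidate_snps(build_position_profile(asn, db), params = p)
  expect_equal(sub_tokens(substitutions(cand$ref, cand$pos, cand$alt)), "G210T")
  expect_equal(attr(cand, "status"), "ok")
  # 19% share -> below min_share, no candidate
  asn19 <- batch_assign(planted_repertoire(db, "IGHV1-8*02", 210, 100, 19), db)
  expect_equal(nrow(call_candidate_snps(build_position_profile(asn19, db),
                                        params = p)), 0)
  # 20% exactly -> fires
  asn20 <- batch_assign(planted_repertoire(db, "IGHV1-8*02", 210, 100, 20), db)
  expect_equal(nrow(call_candidate_snps(build_position_profile(asn20, db),
                                        params = p)), 1)
  # 30% share but 3% discordant at the same position -> hotspot-like, rejected
  base <- db$sequence[match("IGHV1-8*02", db$name)]
  noisy <- dplyr::bind_rows(
    planted_repertoire(db, "IGHV1-8*02", 210, 97, 30, alt = "T"),
    tibble::tibble(id = sprintf("n%02d", 1:3),
                   sequence = rep(apply_substitutions(
                     base, substitutions("G", 210, "C")), 3),
                   multiplicity = 1L)
  )
  profn <- build_position_profile(batch_assign(noisy, db), db)
  expect_equal(nrow(call_candidate_snps(profn, params = p)), 0)
  # masked positions are excluded
  expect_equal(nrow(call_candidate_snps(
    build_position_profile(asn, db),
    params = caller_params(masked_positions = 210L))), 0)
})

test_that("insufficient depth is a distinct outcome, not a negative", {
  asn <- batch_assign(planted_repertoire(db, "IGHV1-8*02", 210, 30, 20), db)
  cand <- call_candidate_snps(build_position_profile(asn, db),
                              params = caller_params(min_unique = 50))
  expect_equal(attr(cand, "status"), "insufficient_depth")
  res <- call_novel_alleles(asn, db)
  expect_equal(res$allele_status$status[
    res$allele_status$allele == "IGHV1-8*02"], "insufficient_depth")
})

test_that("co-occurrence partitions candidates into identical patterns", {
  # three SNPs riding on the same sequences -> one three-substitution allele
  asn3 <- batch_assign(planted_repertoire(
    db, "IGHV4-61*01", c(90, 127, 129), 100, 90,
    alt = c("T", "G", "C")), db)
  res3 <- call_novel_alleles(asn3, db)
  expect_equal(nrow(res3$calls), 1)
  expect_equal(res3$calls$novel_name, "IGHV4-61*01 (C93T_C136G_A138C)")
  expect_equal(nrow(res3$calls$substitutions[[1]]), 3)
  expect_equal(res3$calls$share, 0.9)
  expect_equal(res3$calls$novel_sequence,
               example_novel_alleles()$sequence[
                 example_novel_alleles()$name == "IGHV4-61*01 (C93T_C136G_A138C)"])

  # two candidates that never co-occur -> two single-SNP alleles
  base <- db$sequence[match("IGHV1-8*02", db$name)]
  hap1 <- apply_substitutions(base, substitutions("G", 210, "T"))
  hap2 <- apply_substitutions(base, substitutions("C", 50, "A"))
  two <- tibble::tibble(
    id = sprintf("h%03d", 1:100),
    sequence = c(rep(hap1, 25), rep(hap2, 25), rep(base, 50)),
    multiplicity = 1L
  )
  res2 <- call_novel_alleles(batch_assign(two, db), db)
  expect_equal(nrow(res2$calls), 2)
  expect_equal(sort(vapply(res2$calls$substitutions, nrow, 0L)), c(1L, 1L))
  expect_equal(res2$calls$share, c(0.25, 0.25))

  # singleton pattern at 24% -> one single-SNP call equal to the candidate
  asn1 <- batch_assign(planted_repertoire(db, "IGHV1-8*02", 210, 100, 24,
                                          alt = "T"), db)
  res1 <- call_novel_alleles(batch_assign(
    planted_repertoire(db, "IGHV1-8*02", 210, 100, 24, alt = "T"), db), db)
  expect_equal(res1$calls$novel_name, "IGHV1-8*02 (G234T)")
  expect_equal(res1$calls$share, 0.24)
})

test_that("patterns larger than max_snps are reported out of range", {
  asn <- batch_assign(planted_repertoire(
    db, "IGHV1-8*02", c(20, 60, 100, 140, 180), 100, 40), db)
  prof <- build_position_profile(asn, db)
  cand <- call_candidate_snps(prof, params = caller_params())
  expect_equal(nrow(cand), 5)
  calls <- check_cooccurrence(asn, cand, caller_params(), db)
  expect_equal(nrow(calls), 0)
  expect_equal(length(attr(calls, "out_of_range")), 1)
})

test_that("strict mode gates calling on the ratio screen", {
  # 25% share: ratio 3:1 >= 2 so strict mode does not inspect the class
  asn <- batch_assign(planted_repertoire(db, "IGHV1-8*02", 210, 100, 25), db)
  summ <- compute_mismatch_ratios(asn, caller_params(strict = TRUE))
  cand <- call_candidate_snps(build_position_profile(asn, db), summ,
                              caller_params(strict = TRUE))
  expect_equal(attr(cand, "status"), "not_triggered")
  # 60% share triggers and calls
  asn2 <- batch_assign(planted_repertoire(db, "IGHV1-8*02", 210, 100, 60), db)
  summ2 <- compute_mismatch_ratios(asn2, caller_params(strict = TRUE))
  cand2 <- call_candidate_snps(build_position_profile(asn2, db), summ2,
                               caller_params(strict = TRUE))
  expect_equal(nrow(cand2), 1)
})

test_that("thresholds are monotone: tightening never adds calls", {
  gt <- simulate_genotype(db, tibble::tibble(
    gene = "IGHV1-8", copies = 2L, novel = "IGHV1-8*02 (G234T)"))
  reps <- simulate_igm_repertoire(gt, sim_params(n_unique = 800), seed = 17)
  asn <- batch_assign(reps, db)
  base_calls <- call_novel_alleles(asn, db, caller_params())$calls$novel_name
  for (ms in c(0.3, 0.45, 0.6)) {
    tightened <- call_novel_alleles(asn, db,
                                    caller_params(min_share = ms))$calls$novel_name
    expect_true(all(tightened %in% base_calls))
  }
  for (md in c(0.015, 0.01, 0.005)) {
    tightened <- call_novel_alleles(asn, db,
                                    caller_params(max_discordant = md))$calls$novel_name
    expect_true(all(tightened %in% base_calls))
  }
})

test_that("homozygous novel genotypes show the empty-perfect-class signature", {
  gt <- simulate_genotype(db, tibble::tibble(
    gene = "IGHV4-59", copies = 2L,
    alleles = list(NULL), novel = "IGHV4-59*01 (T109C)"))
  gt$sequence[1] <- gt$sequence[2]  # both copies novel
  gt$allele_name[1] <- gt$allele_name[2]
  gt$is_novel[1] <- TRUE
  reps <- simulate_igm_repertoire(gt, sim_params(n_unique = 1000), seed = 23)
  asn <- batch_assign(reps, db)
  res <- call_novel_alleles(asn, db)
  expect_equal(res$calls$novel_name, "IGHV4-59*01 (T109C)")
  expect_gte(res$calls$share, 0.95)
  r <- res$ratios[res$ratios$allele == "IGHV4-59*01", ]
  expect_lte(r$n[r$k == 0] / r$n_total[1], 0.02)
})

test_that("heterozygous 1-of-4 novel alleles are recovered across replicates", {
  spec <- tibble::tibble(
    gene = "IGHV1-8", copies = 4L, novel = "IGHV1-8*02 (G234T)")
  gt <- simulate_genotype(db, spec)
  hits <- 0L
  n_rep <- 200L
  for (s in seq_len(n_rep)) {
    reps <- simulate_igm_repertoire(gt, sim_params(n_unique = 1000), seed = 1000 + s)
    res <- call_novel_alleles(batch_assign(reps, db), db)
    if ("IGHV1-8*02 (G234T)" %in% res$calls$novel_name) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("a full-length call over a truncated record is annotated, not suppressed", {
  novel <- plant(db, "IGHV1-69*01", 148, "A")
  trunc <- substr(novel, 11, nchar(novel) - 10)
  db2 <- validate_germline_db(dplyr::bind_rows(
    db, dplyr::mutate(db[db$name == "IGHV1-69*01", ],
                      name = "IGHV1-69*07", sequence = trunc,
                      position_map = list(NULL))
  ))
  reads <- tibble::tibble(
    id = sprintf("x%03d", 1:200),
    sequence = c(rep(novel, 80),
                 rep(db$sequence[match("IGHV1-69*01", db$name)], 120)),
    multiplicity = 1L
  )
  res <- call_novel_alleles(batch_assign(reads, db2), db2)
  expect_equal(res$calls$novel_name, "IGHV1-69*01 (G163A)")
  expect_equal(res$calls$note, "extends truncated allele IGHV1-69*07")
})

test_that("novel sequences differ from their base exactly at the called positions", {
  asn <- batch_assign(planted_repertoire(
    db, "IGHV4-61*01", c(90, 127, 129), 100, 50, alt = c("T", "G", "C")), db)
  res <- call_novel_alleles(asn, db)
  for (r in seq_len(nrow(res$calls))) {
    base <- db$sequence[match(res$calls$base_allele[r], db$name)]
    d <- diff_sequences(base, res$calls$novel_sequence[r])
    expect_equal(as.data.frame(d),
                 as.data.frame(res$calls$substitutions[[r]]))
  }
})
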