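db <- example_germline_db()
novel_18 <- "IGHV1-8*02 (G234T)"

test_that("read filtering keeps the allele group and discards distant homology", {
  base <- db$sequence[match("IGHV1-8*02", db$name)]
  # reads simulated from the base allele only: all retained, none novel-exact
  f <- filter_reads_to_allele_group(rep(base, 40), db, novel_18)
  cnt <- attr(f, "counts")
  expect_equal(unname(cnt["n_retained"]), 40L)
  cand <- attr(f, "candidate")
  tally <- tally_exact_matches(f, cand$ref_sequence, cand$novel_sequence)
  expect_equal(tally$n_novel_exact, 0L)
  expect_equal(tally$n_ref_exact, 40L)

  # 50:50 mixture with a homologous allele of a different gene: half retained
  other <- db$sequence[match("IGHV1-69*01", db$name)]
  f2 <- filter_reads_to_allele_group(c(rep(base, 30), rep(other, 30)), db, novel_18)
  cnt2 <- attr(f2, "counts")
  expect_equal(unname(cnt2["n_retained"]), 30L)
  expect_equal(unname(cnt2["n_other_gene"]), 30L)

  # a read far from every allele of the group is discarded
  far <- plant(db, "IGHV1-8*02", c(20, 50, 80, 110, 140, 170, 200, 230))
  f3 <- filter_reads_to_allele_group(c(rep(base, 10), far), db, novel_18)
  cnt3 <- attr(f3, "counts")
  expect_equal(unname(cnt3["n_retained"]), 10L)
  expect_equal(unname(cnt3["n_distant"]), 1L)

  # count conservation across the filter
  for (cnt_i in list(cnt, cnt2, cnt3)) {
    expect_equal(unname(cnt_i["n_input"]),
                 sum(cnt_i[c("n_retained", "n_distant", "n_indel",
                             "n_other_gene", "n_unassignable")]))
  }
})

test_that("exact-match tallies are strict and count-conserving", {
  cand <- resolve_novel_name(db, novel_18)
  ref <- db$sequence[match("IGHV1-8*02", db$name)]
  novel <- cand$sequence
  reads <- c(rep(novel, 29), rep(ref, 71))
  f <- filter_reads_to_allele_group(reads, db, novel_18)
  tally <- tally_exact_matches(f, ref, novel)
  expect_equal(tally$n_novel_exact, 29L)
  expect_equal(tally$n_ref_exact, 71L)
  expect_equal(tally$novel_fraction, 0.29)
  expect_equal(tally$n_filtered,
               tally$n_ref_exact + tally$n_novel_exact + tally$n_other)
  v <- call_validation(tally)
  expect_equal(v$status, "positive")

  # a single sequencing error outside the SNP position lands in n_other
  err_read <- plant(db, "IGHV1-8*02", 150)
  f2 <- filter_reads_to_allele_group(c(rep(ref, 30), err_read), db, novel_18)
  t2 <- tally_exact_matches(f2, ref, novel)
  expect_equal(t2$n_other, 1L)
  expect_equal(t2$n_ref_exact, 30L)

  # 0 novel-exact reads -> fraction 0 -> negative
  t3 <- tally_exact_matches(f2[f2$sequence == ref, ], ref, novel)
  expect_equal(t3$novel_fraction, 0)
  expect_equal(call_validation(t3)$status, "negative")
})

test_that("the comparison region must contain all SNP positions", {
  ref <- db$sequence[match("IGHV1-8*02", db$name)]
  cand <- resolve_novel_name(db, novel_18)
  # amplicon ending 5 nt past the SNP: the 14 nt primer margin swallows it
  short <- substr(ref, 1, 215)
  f <- filter_reads_to_allele_group(rep(short, 25), db, novel_18)
  expect_error(tally_exact_matches(f, ref, cand$sequence),
               "primer design violation")
  expect_error(tally_exact_matches(f, ref, substr(ref, 1, 100)),
               "equal length")
  expect_error(tally_exact_matches(f, ref, ref), "identical")
})

test_that("validation status and zygosity hints follow the thresholds", {
  mk <- function(n_ref, n_novel, n_other = 0L) {
    tibble::tibble(n_filtered = n_ref + n_novel + n_other,
                   n_ref_exact = n_ref, n_novel_exact = n_novel,
                   n_other = n_other,
                   novel_fraction = n_novel / (n_ref + n_novel))
  }
  v <- call_validation(mk(100L, 100L))
  expect_equal(v$status, "positive")
  expect_equal(v$zygosity_hint, "heterozygous-like")
  v2 <- call_validation(mk(0L, 150L))
  expect_equal(v2$status, "positive")
  expect_equal(v2$zygosity_hint, "homozygous-like")
  # the failed-to-amplify state: depth below the floor is N.D., not negative
  v3 <- call_validation(mk(3L, 2L))
  expect_equal(v3$status, "failed")
  # boundary: exactly 20% of tallied reads is positive
  v4 <- call_validation(mk(80L, 20L))
  expect_equal(v4$status, "positive")
  v5 <- call_validation(mk(81L, 19L))
  expect_equal(v5$status, "negative")
})

test_that("copy-number flags count distinct exact allele sequences", {
  gt3 <- simulate_genotype(db, tibble::tibble(
    gene = "IGHV1-69", copies = 3L,
    alleles = list(c("IGHV1-69*01", "IGHV1-69*90", "IGHV1-69*01")),
    novel = "IGHV1-69*01 (G163A)"
  ))
  p <- sim_params(gdna_depth = 500, seq_error_rate = 0.001)
  flags <- 0L
  for (s in 1:20) {
    reads <- simulate_gdna_reads(gt3, "IGHV1-69", p, seed = s)
    f <- filter_reads_to_allele_group(reads, db, "IGHV1-69*01 (G163A)")
    r <- detect_cnv(f, "IGHV1-69", attr(f, "db"))
    expect_equal(r$distinct_alleles, 3L)
    if (r$cnv_flag) flags <- flags + 1L
  }
  expect_gte(flags, 19L)

  # diploid norm: 2 distinct alleles, no flag
  gt2 <- simulate_genotype(db, tibble::tibble(
    gene = "IGHV1-69", copies = 2L, novel = "IGHV1-69*01 (G163A)"))
  reads2 <- simulate_gdna_reads(gt2, "IGHV1-69", p, seed = 5)
  f2 <- filter_reads_to_allele_group(reads2, db, "IGHV1-69*01 (G163A)")
  r2 <- detect_cnv(f2, "IGHV1-69", attr(f2, "db"))
  expect_equal(r2$distinct_alleles, 2L)
  expect_false(r2$cnv_flag)
})

test_that("deletion flags require absence from both repertoire and gDNA", {
  gt <- simulate_genotype(db, tibble::tibble(
    gene = c("IGHV1-8", "IGHV4-31"), copies = c(2L, 0L)))
  reads <- simulate_gdna_reads(gt, "IGHV4-31", sim_params(), seed = 3)
  expect_equal(nrow(reads), 0)
  expect_true(attr(reads, "deletion"))
  reps <- simulate_igm_repertoire(gt, sim_params(n_unique = 300), seed = 3)
  asn <- batch_assign(reps, db)
  f <- filter_reads_to_allele_group(reads, db, "IGHV4-31*02 (C198T)")
  d <- detect_deletion(asn, f, "IGHV4-31", db)
  expect_true(d$deletion_flag)

  # present in the repertoire only: no deletion, annotated
  d2 <- detect_deletion(asn, f, "IGHV1-8", db)
  expect_false(d2$deletion_flag)
  expect_equal(d2$note, "gDNA dropout?")
})

test_that("simulated het/hom fractions and the no-novel null behave", {
  p <- sim_params(gdna_depth = 500, seq_error_rate = 0.001)
  het <- simulate_genotype(db, tibble::tibble(
    gene = "IGHV1-8", copies = 2L, novel = novel_18))
  in_band <- 0L
  for (s in 1:20) {
    v <- validate_candidate(simulate_gdna_reads(het, "IGHV1-8", p, seed = 100 + s),
                            db, novel_18)
    expect_equal(v$status, "positive")
    if (v$novel_fraction >= 0.4 && v$novel_fraction <= 0.6) in_band <- in_band + 1L
  }
  expect_gte(in_band, 19L)

  hom <- het
  hom$sequence[1] <- hom$sequence[2]
  hom$is_novel[1] <- TRUE
  vh <- validate_candidate(simulate_gdna_reads(hom, "IGHV1-8", p, seed = 7),
                           db, novel_18)
  expect_gte(vh$novel_fraction, 0.95)
  expect_equal(vh$zygosity_hint, "homozygous-like")

  # reference-only reads: novel_fraction exactly 0, every replicate
  ref_only <- simulate_genotype(db, tibble::tibble(gene = "IGHV1-8", copies = 2L))
  for (s in 1:5) {
    v0 <- validate_candidate(simulate_gdna_reads(ref_only, "IGHV1-8", p, seed = s),
                             db, novel_18)
    expect_identical(v0$novel_fraction, 0)
    expect_equal(v0$status, "negative")
  }
})

test_that("under-depth libraries come back as failed / N.D.", {
  gt <- simulate_genotype(db, tibble::tibble(
    gene = "IGHV1-8", copies = 2L, novel = novel_18))
  reads <- simulate_gdna_reads(gt, "IGHV1-8",
                               sim_params(gdna_depth = 5), seed = 2)
  v <- validate_candidate(reads, db, novel_18)
  expect_equal(v$status, "failed")
  # empty read set is the hard failure mode
  v0 <- validate_candidate(tibble::tibble(id = character(),
                                          sequence = character()),
                           db, novel_18)
  expect_equal(v0$status, "failed")
})

test_that("concordance tables mirror the prediction/validation layout", {
  preds <- tibble::tibble(
    subject = c("1", "1", "2", "2"),
    candidate = rep(c("A (G10T)", "B (C5A)"), 2),
    predicted = c(TRUE, FALSE, FALSE, FALSE)
  )
  vals <- tibble::tibble(
    subject = c("1", "1", "2", "2"),
    candidate = rep(c("A (G10T)", "B (C5A)"), 2),
    status = c("positive", "negative", "failed", "negative"),
    cnv_flag = c(TRUE, FALSE, FALSE, FALSE),
    deletion_flag = c(FALSE, FALSE, FALSE, TRUE)
  )
  tab <- build_concordance_table(preds, vals)
  long <- attr(tab, "long")
  expect_equal(long$cell[1], "+/+^a")
  expect_equal(long$cell[3], "-/N.D.")
  expect_equal(long$cell[4], "-/-^b")
  expect_equal(attr(tab, "concordance"), 1)
  expect_equal(dim(tab), c(2L, 3L))
  expect_error(build_concordance_table(preds[1:3, ], vals), "orphans")
})
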