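#' Validation parameters
#'
#' Thresholds for confirming predicted novel alleles in targeted genomic-DNA
#' amplicon reads.  Filtered reads matching the reference or the novel
#' sequence exactly are tallied; a sample is a positive hit when the novel
#' sequence accounts for at least `novel_read_threshold` of the tallied
#' reads.
#'
#' @param novel_read_threshold Fraction of tallied reads that must match the
#'   novel sequence exactly (default 0.20, matching the prediction
#'   threshold).
#' @param min_tallied Minimum tallied reads for a confident call; below it
#'   the outcome is `"failed"` (the library-failed-to-amplify state), not
#'   negative.
#' @param primer_margin Bases trimmed from each amplicon end before exact
#'   comparison; primers are designed at least 14 nt away from the
#'   predicted mismatch positions, so the margin provably retains all SNPs.
#' @param cnv_min_alleles Distinct allele sequences per gene that flag a
#'   copy-number variant (default 3: more than a diploid pair).
#' @param max_mismatch Reads farther than this many substitutions from every
#'   allele of the target group are discarded as homology noise (default
#'   4 + 2: the largest substitution set called, plus sequencing-error slack).
#' @param denominator `"tallied"` (ref-exact + novel-exact; the default) or
#'   `"filtered"` (all retained reads) for the novel fraction.
#' @return A list of class `validation_params`.
#' @export
validation_params <- function(novel_read_threshold = 0.20, min_tallied = 20L,
                              primer_margin = 14L, cnv_min_alleles = 3L,
                              max_mismatch = 6L,
                              denominator = c("tallied", "filtered")) {
  stopifnot(novel_read_threshold > 0, novel_read_threshold <= 1,
            primer_margin >= 0L, min_tallied >= 1L, cnv_min_alleles >= 1L)
  structure(list(novel_read_threshold = novel_read_threshold,
                 min_tallied = as.integer(min_tallied),
                 primer_margin = as.integer(primer_margin),
                 cnv_min_alleles = as.integer(cnv_min_alleles),
                 max_mismatch = as.integer(max_mismatch),
                 denominator = match.arg(denominator)),
            class = "validation_params")
}

#' Duplicated-gene groups
#'
#' IGHV1-69/IGHV1-69D and IGHV3-30/IGHV3-30-5 arose by segmental duplication
#' and share allele pools; for copy-number and deletion accounting they are
#' treated as one gene group.  Supply your own list to override.
#'
#' @return A named list mapping group label to member genes.
#' @export
default_gene_groups <- function() {
  list("IGHV1-69" = c("IGHV1-69", "IGHV1-69D"),
       "IGHV3-30" = c("IGHV3-30", "IGHV3-30-5"))
}

gene_group_of <- function(gene, gene_groups = default_gene_groups()) {
  for (label in names(gene_groups)) {
    if (gene %in% gene_groups[[label]]) return(label)
  }
  gene
}

group_members <- function(gene, gene_groups = default_gene_groups()) {
  label <- gene_group_of(gene, gene_groups)
  unique(c(label, gene_groups[[label]], gene))
}

#' Filter genomic-DNA reads to a candidate's allele group
#'
#' Reads are assigned against the database augmented with the candidate
#' novel sequence; those whose best match is the base allele, the novel
#' allele, or another allele of the same gene (group) are retained.  Reads
#' with indels or more than `max_mismatch` substitutions to their best match
#' are discarded as distant-homology noise.
#'
#' @param reads Merged amplicon reads (tibble with `id`/`sequence`, or a
#'   character vector).
#' @param db A [germline_db()].
#' @param candidate A novel-allele call: one row of a
#'   [call_novel_alleles()] call table, or a novel-allele name string.
#' @param params [validation_params()].
#' @param gene_groups See [default_gene_groups()].
#' @param min_overlap Passed to [batch_assign()].
#' @return The retained assignment rows, with attributes `counts` (input /
#'   retained / discarded tallies), `db` (the augmented database) and
#'   `candidate` (resolved base, novel name, sequences).
#' @export
filter_reads_to_allele_group <- function(reads, db, candidate,
                                         params = validation_params(),
                                         gene_groups = default_gene_groups(),
                                         min_overlap = 100L) {
  cand <- resolve_candidate(db, candidate)
  db_aug <- add_novel_allele(db, cand$base, cand$substitutions)
  if (is.character(reads)) {
    reads <- tibble::tibble(id = sprintf("r%06d", seq_along(reads)),
                            sequence = reads, multiplicity = 1L)
  }
  if (nrow(reads) == 0L) {
    out <- empty_assignments()
    attr(out, "counts") <- c(n_input = 0L, n_retained = 0L, n_distant = 0L,
                             n_indel = 0L, n_other_gene = 0L, n_unassignable = 0L)
    attr(out, "db") <- db_aug
    attr(out, "candidate") <- cand
    return(out)
  }
  asn <- batch_assign(reads, db_aug, min_overlap = min_overlap)
  target <- group_members(allele_gene(cand$base), gene_groups)
  gene_of <- db_aug$gene[match(asn$allele, db_aug$name)]
  in_group <- !is.na(gene_of) & gene_of %in% target
  keep <- asn$status == "assigned" & in_group & asn$n_mismatches <= params$max_mismatch
  out <- asn[keep, ]
  attr(out, "counts") <- c(
    n_input = nrow(asn),
    n_retained = sum(keep),
    n_distant = sum(asn$status == "assigned" & in_group &
                      asn$n_mismatches > params$max_mismatch),
    n_indel = sum(asn$status == "indel"),
    n_other_gene = sum(asn$status == "assigned" & !in_group),
    n_unassignable = sum(asn$status %in% c("unassignable", "invalid"))
  )
  attr(out, "db") <- db_aug
  attr(out, "candidate") <- cand
  class(out) <- c("ig_assignments", class(tibble::tibble()))
  out
}

resolve_candidate <- function(db, candidate) {
  if (is.character(candidate)) {
    res <- resolve_novel_name(db, candidate)
    list(base = res$base, substitutions = res$substitutions,
         novel_name = candidate, novel_sequence = res$sequence,
         ref_sequence = db$sequence[match(res$base, db$name)])
  } else {
    stopifnot(is.data.frame(candidate), nrow(candidate) == 1L)
    list(base = candidate$base_allele, substitutions = candidate$substitutions[[1]],
         novel_name = candidate$novel_name, novel_sequence = candidate$novel_sequence,
         ref_sequence = db$sequence[match(candidate$base_allele, db$name)])
  }
}

empty_assignments <- function() {
  out <- tibble::tibble(
    query_id = character(), sequence = character(), multiplicity = integer(),
    allele = character(), aligned_start = integer(), aligned_end = integer(),
    query_start = integer(), n_mismatches = integer(), mismatches = list(),
    has_indel = logical(), status = character()
  )
  class(out) <- c("ig_assignments", class(tibble::tibble()))
  out
}

#' Tally exact matches to reference and novel sequences
#'
#' For every filtered read the comparison region is the intersection of the
#' read's aligned span with the allele span, trimmed by `primer_margin` at
#' both amplicon ends.  A read counts as reference-exact or novel-exact only
#' if it equals the corresponding sequence base-for-base over the whole
#' region; anything else (including reads with a single sequencing error
#' outside the SNP positions) lands in `n_other`.
#'
#' @param filtered Output of [filter_reads_to_allele_group()].
#' @param ref_seq,novel_seq Equal-length reference and novel sequences
#'   differing at one or more positions.
#' @param params [validation_params()].
#' @return One-row tibble: `n_filtered`, `n_ref_exact`, `n_novel_exact`,
#'   `n_other`, `novel_fraction` (`NA` when no read matched either
#'   sequence).
#' @export
tally_exact_matches <- function(filtered, ref_seq, novel_seq,
                                params = validation_params()) {
  if (nchar(ref_seq) != nchar(novel_seq)) {
    stop("reference and novel sequence must be coordinate-aligned ",
         "(equal length)", call. = FALSE)
  }
  snps <- diff_sequences(ref_seq, novel_seq)
  if (nrow(snps) == 0L) {
    stop("reference and novel sequence are identical", call. = FALSE)
  }
  margin <- params$primer_margin
  a_start <- filtered$aligned_start
  a_end <- pmin(filtered$aligned_end, nchar(ref_seq))
  r_start <- a_start + margin
  r_end <- a_end - margin
  bad <- r_start > r_end |
    (nrow(filtered) > 0L &
       (r_start > min(snps$pos) | r_end < max(snps$pos)))
  if (any(bad)) {
    k <- which(bad)[1]
    stop("comparison region [", r_start[k], ", ", r_end[k], "] of read ",
         filtered$query_id[k], " does not contain all predicted SNP ",
         "positions; primer design violation", call. = FALSE)
  }
  q0 <- filtered$query_start
  read_piece <- substr(filtered$sequence, r_start - a_start + q0,
                       r_end - a_start + q0)
  is_ref <- read_piece == substring(ref_seq, r_start, r_end)
  is_novel <- !is_ref & read_piece == substring(novel_seq, r_start, r_end)
  n_ref <- sum(is_ref)
  n_novel <- sum(is_novel)
  n_other <- nrow(filtered) - n_ref - n_novel
  denom <- if (params$denominator == "tallied") n_ref + n_novel else nrow(filtered)
  tibble::tibble(
    n_filtered = nrow(filtered),
    n_ref_exact = n_ref,
    n_novel_exact = n_novel,
    n_other = n_other,
    novel_fraction = if (denom > 0L) n_novel / denom else NA_real_
  )
}

#' Call a validation outcome from a tally
#'
#' Positive when the novel fraction reaches the read threshold on at least
#' `min_tallied` tallied reads; `"failed"` (not negative) below the depth
#' floor.  The zygosity hint is a descriptive annotation only: novel
#' fractions between 0.2 and 0.8 look heterozygous, at or above 0.9
#' homozygous.
#'
#' @param tally A [tally_exact_matches()] row.
#' @param params [validation_params()].
#' @return One-row tibble: `status` (`positive`/`negative`/`failed`),
#'   `novel_fraction`, `zygosity_hint`, and the tally counts.
#' @export
call_validation <- function(tally, params = validation_params()) {
  denom <- if (params$denominator == "tallied") {
    tally$n_ref_exact + tally$n_novel_exact
  } else {
    tally$n_filtered
  }
  f <- tally$novel_fraction
  status <- if (denom < params$min_tallied) {
    "failed"
  } else if (!is.na(f) && f >= params$novel_read_threshold) {
    "positive"
  } else {
    "negative"
  }
  zyg <- if (status != "positive" || is.na(f)) {
    "indeterminate"
  } else if (f >= 0.9) {
    "homozygous-like"
  } else if (f >= 0.2 && f <= 0.8) {
    "heterozygous-like"
  } else {
    "indeterminate"
  }
  dplyr::bind_cols(
    tibble::tibble(status = status, zygosity_hint = zyg),
    tally[, c("n_filtered", "n_ref_exact", "n_novel_exact", "n_other",
              "novel_fraction")]
  )
}

#' Validate one candidate against genomic-DNA reads
#'
#' Convenience driver: filter, tally, call.
#'
#' @inheritParams filter_reads_to_allele_group
#' @param subject Optional subject identifier carried into the result.
#' @return One-row tibble with `subject`, `candidate`, the tally counts,
#'   `novel_fraction`, `status` and `zygosity_hint`.
#' @export
validate_candidate <- function(reads, db, candidate,
                               params = validation_params(),
                               gene_groups = default_gene_groups(),
                               subject = NA_character_) {
  filtered <- filter_reads_to_allele_group(reads, db, candidate, params,
                                           gene_groups)
  cand <- attr(filtered, "candidate")
  if (nrow(filtered) == 0L) {
    return(tibble::tibble(
      subject = subject, candidate = cand$novel_name,
      status = "failed", zygosity_hint = "indeterminate",
      n_filtered = 0L, n_ref_exact = 0L, n_novel_exact = 0L, n_other = 0L,
      novel_fraction = NA_real_
    ))
  }
  tally <- tally_exact_matches(filtered, cand$ref_sequence,
                               cand$novel_sequence, params)
  out <- call_validation(tally, params)
  dplyr::bind_cols(tibble::tibble(subject = subject,
                                  candidate = cand$novel_name), out)
}

#' Copy-number flag from genomic-DNA assignments
#'
#' Counts the distinct allele *sequences* of a gene group supported by
#' exact-matching reads (at least `min_tallied / 2` reads with zero
#' mismatches each); more than two distinct alleles flags a copy-number
#' variant.  Duplicated-gene pairs (see [default_gene_groups()]) are pooled.
#'
#' @param gdna_assignments Assignments of filtered genomic-DNA reads (e.g.
#'   pooled [filter_reads_to_allele_group()] output), with the database they
#'   were assigned against.
#' @param gene Gene (group) of interest.
#' @param db The (augmented) [germline_db()].
#' @param params [validation_params()].
#' @param gene_groups See [default_gene_groups()].
#' @return One-row tibble: `gene`, `distinct_alleles`, `cnv_flag`.
#' @export
detect_cnv <- function(gdna_assignments, gene, db,
                       params = validation_params(),
                       gene_groups = default_gene_groups()) {
  members <- group_members(gene, gene_groups)
  gene_of <- db$gene[match(gdna_assignments$allele, db$name)]
  grp <- gdna_assignments[gdna_assignments$status == "assigned" &
                            !is.na(gene_of) & gene_of %in% members &
                            gdna_assignments$n_mismatches == 0L, , drop = FALSE]
  min_support <- max(1L, params$min_tallied %/% 2L)
  support <- table(grp$allele)
  supported <- names(support)[support >= min_support]
  # duplicate records with identical sequences count once
  n_distinct <- length(unique(db$sequence[match(supported, db$name)]))
  tibble::tibble(
    gene = gene_group_of(gene, gene_groups),
    distinct_alleles = n_distinct,
    cnv_flag = n_distinct >= params$cnv_min_alleles
  )
}

#' Gene-deletion flag
#'
#' A gene (group) is flagged as possibly deleted only when it is absent from
#' *both* the expressed repertoire and the genomic-DNA reads; presence in
#' just one source is annotated instead.
#'
#' @param repertoire_assignments,gdna_assignments Assignment tables.
#' @param gene Gene (group) of interest.
#' @param db The [germline_db()] used for the assignments.
#' @param gene_groups See [default_gene_groups()].
#' @return One-row tibble: `gene`, `n_repertoire`, `n_gdna`,
#'   `deletion_flag`, `note`.
#' @export
detect_deletion <- function(repertoire_assignments, gdna_assignments, gene,
                            db, gene_groups = default_gene_groups()) {
  members <- group_members(gene, gene_groups)
  count_in <- function(asn) {
    gene_of <- db$gene[match(asn$allele, db$name)]
    sum(asn$status == "assigned" & !is.na(gene_of) & gene_of %in% members)
  }
  n_rep <- count_in(repertoire_assignments)
  n_gdna <- count_in(gdna_assignments)
  tibble::tibble(
    gene = gene_group_of(gene, gene_groups),
    n_repertoire = n_rep,
    n_gdna = n_gdna,
    deletion_flag = n_rep == 0L && n_gdna == 0L,
    note = if (n_rep > 0L && n_gdna == 0L) "gDNA dropout?"
           else if (n_rep == 0L && n_gdna > 0L) "repertoire dropout?"
           else ""
  )
}

#' Prediction/validation concordance table
#'
#' One cell per subject and candidate combining the repertoire prediction
#' and the genomic-DNA validation outcome: `+/+`, `-/-`, `+/-`, `-/+` or
#' `-/N.D.` (validation failed), with `^a` appended where a copy-number
#' variant was flagged and `^b` where the gene is possibly deleted.
#'
#' @param predictions Tibble with `subject`, `candidate`, `predicted`
#'   (logical).
#' @param validations Tibble with `subject`, `candidate`, `status`, and
#'   optionally `cnv_flag`, `deletion_flag`.
#' @return A tibble of class `ig_concordance` in wide layout (one row per
#'   subject, one column per candidate) with attributes `long` (the joined
#'   long table) and `concordance` (agreement rate over non-failed cells).
#' @export
build_concordance_table <- function(predictions, validations) {
  key_p <- paste(predictions$subject, predictions$candidate)
  key_v <- paste(validations$subject, validations$candidate)
  orphans <- c(setdiff(key_p, key_v), setdiff(key_v, key_p))
  if (length(orphans) > 0L) {
    stop("prediction/validation keys do not match; orphans: ",
         paste(orphans, collapse = "; "), call. = FALSE)
  }
  long <- dplyr::inner_join(predictions, validations,
                            by = c("subject", "candidate"))
  if (!"cnv_flag" %in% names(long)) long$cnv_flag <- FALSE
  if (!"deletion_flag" %in% names(long)) long$deletion_flag <- FALSE
  pred_sym <- ifelse(long$predicted, "+", "-")
  val_sym <- dplyr::case_match(long$status,
                               "positive" ~ "+",
                               "negative" ~ "-",
                               "failed" ~ "N.D.")
  long$cell <- paste0(pred_sym, "/", val_sym,
                      ifelse(long$cnv_flag, "^a", ""),
                      ifelse(long$deletion_flag, "^b", ""))
  long$concordant <- ifelse(long$status == "failed", NA,
                            long$predicted == (long$status == "positive"))
  wide <- tidyr::pivot_wider(long[, c("subject", "candidate", "cell")],
                             names_from = "candidate", values_from = "cell")
  attr(wide, "long") <- long
  attr(wide, "concordance") <- mean(long$concordant, na.rm = TRUE)
  class(wide) <- c("ig_concordance", class(tibble::tibble()))
  wide
}

#' @export
print.ig_concordance <- function(x, ...) {
  cat("<concordance table> prediction/validation agreement: ",
      sprintf("%.1f%%", 100 * attr(x, "concordance")),
      " (excluding N.D. cells)\n", sep = "")
  NextMethod()
}

#' Plot validation outcomes
#'
#' Repertoire novel-allele share against genomic-DNA novel-read fraction,
#' one point per subject-candidate pair, with the 20% calling thresholds.
#' True positives cluster top-right (or mid-right for heterozygotes);
#' negatives sit at the origin.
#'
#' @param object A tibble with `share` (repertoire) and `novel_fraction`
#'   (genomic DNA) columns, e.g. a joined prediction/validation table.
#' @param threshold Calling threshold drawn on both axes.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_validation <- function(object, threshold = 0.20, ...) {
  df <- tibble::as_tibble(object)
  df$share[is.na(df$share)] <- 0
  ggplot2::ggplot(df, ggplot2::aes(x = 100 * .data$share,
                                   y = 100 * .data$novel_fraction)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = 100 * threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_hline(yintercept = 100 * threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "% unique IgM sequences with novel pattern",
                  y = "% gDNA reads matching novel sequence") +
    ggplot2::theme_minimal()
}
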