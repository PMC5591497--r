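# Bundled example set: six experimentally validated novel human IGHV alleles
# (heavy-chain V genes of an African malaria-cohort population) together with
# their nearest reference alleles.  Sequences are the full-length novel
# alleles; the references are reconstructed by inverting the named
# substitutions.  CDR1/CDR2 lengths and the FR3 position-73 gap flag are the
# standard IMGT delimitations for these genes and drive the IMGT position
# maps (see imgt_position_map), so that substitution names reproduce the
# published IMGT-coordinate forms.

.ighv_examples <- tibble::tibble(
  name = c(
    "IGHV1-8*02 (G234T)",
    "IGHV1-69*01 (G163A)",
    "IGHV3-30*02 (T201C)",
    "IGHV4-31*02 (C198T)",
    "IGHV4-59*01 (T109C)",
    "IGHV4-61*01 (C93T_C136G_A138C)"
  ),
  sequence = c(
    paste0(
      "CAGGTGCAGCTGGTGCAGTCTGGGGCTGAGGTGAAGAAGCCTGGGGCCTCAGTGAAGGTCTCCTGCAAGGCTTCTGGATACACCTTCACC",
      "AGCTATGATATCAACTGGGTGCGACAGGCCACTGGACAAGGGCTTGAGTGGATGGGATGGATGAACCCTAACAGTGGTAACACAGGCTAT",
      "GCACAGAAGTTCCAGGGCAGAGTCACCATTACCAGGAACACCTCCATAAGCACAGCCTACATGGAGCTGAGCAGCCTGAGATCTGAGGAC",
      "ACGGCCGTGTATTACTGTGCGAGAGG"),
    paste0(
      "CAGGTGCAGCTGGTGCAGTCTGGGGCTGAGGTGAAGAAGCCTGGGTCCTCGGTGAAGGTCTCCTGCAAGGCTTCTGGAGGCACCTTCAGC",
      "AGCTATGCTATCAGCTGGGTGCGACAGGCCCCTGGACAAGGGCTTGAGTGGATGGGAAGGATCATCCCTATCTTTGGTACAGCAAACTAC",
      "GCACAGAAGTTCCAGGGCAGAGTCACGATTACCGCGGACGAATCCACGAGCACAGCCTACATGGAGCTGAGCAGCCTGAGATCTGAGGAC",
      "ACGGCCGTGTATTACTGTGCGAGAGA"),
    paste0(
      "CAGGTGCAGCTGGTGGAGTCTGGGGGAGGCGTGGTCCAGCCTGGGGGGTCCCTGAGACTCTCCTGTGCAGCGTCTGGATTCACCTTCAGT",
      "AGCTATGGCATGCACTGGGTCCGCCAGGCTCCAGGCAAGGGGCTGGAGTGGGTGGCATTTATACGGTATGATGGAAGTAATAAATACTAC",
      "GCAGACTCCGTGAAGGGCCGATTCACCATCTCCAGAGACAATTCCAAGAACACGCTGTATCTGCAAATGAACAGCCTGAGAGCTGAGGAC",
      "ACGGCTGTGTATTACTGTGCGAAAGA"),
    paste0(
      "CAGGTGCAGCTGCAGGAGTCGGGCCCAGGACTGGTGAAGCCTTCACAGACCCTGTCCCTCACCTGTACTGTCTCTGGTGGCTCCATCAGC",
      "AGTGGTGGTTACTACTGGAGCTGGATCCGCCAGCACCCAGGGAAGGGCCTGGAGTGGATTGGGTACATCTATTACAGTGGGAGCACCTAT",
      "TACAACCCGTCCCTCAAGAGTCGAGTTACCATATCAGTAGACACGTCTAAGAACCAGTTCTCCCTGAAGCTGAGCTCTGTGACTGCCGCG",
      "GACACGGCCGTGTATTACTGTGCGAGAGA"),
    paste0(
      "CAGGTGCAGCTGCAGGAGTCGGGCCCAGGACTGGTGAAGCCTTCGGAGACCCTGTCCCTCACCTGCACTGTCTCTGGTGGCTCCATCAGT",
      "AGTCACTACTGGAGCTGGATCCGGCAGCCCCCAGGGAAGGGACTGGAGTGGATTGGGTATATCTATTACAGTGGGAGCACCAACTACAAC",
      "CCCTCCCTCAAGAGTCGAGTCACCATATCAGTAGACACGTCCAAGAACCAGTTCTCCCTGAAGCTGAGCTCTGTGACCGCTGCGGACACG",
      "GCCGTGTATTACTGTGCGAGAGA"),
    paste0(
      "CAGGTGCAGCTGCAGGAGTCGGGCCCAGGACTGGTGAAGCCTTCGGAGACCCTGTCCCTCACCTGCACTGTCTCTGGTGGCTCCGTCAGT",
      "AGTGGTAGTTACTACTGGAGCTGGATCCGGCAGCCCGCCGGGAAGGGACTGGAGTGGATTGGGTATATCTATTACAGTGGGAGCACCAAC",
      "TACAACCCCTCCCTCAAGAGTCGAGTCACCATATCAGTAGACACGTCCAAGAACCAGTTCTCCCTGAAGCTGAGCTCTGTGACCGCTGCG",
      "GACACGGCCGTGTATTACTGTGCGAGAGA")
  ),
  cdr1_len = c(8L, 8L, 8L, 10L, 8L, 10L),
  cdr2_len = c(8L, 8L, 8L, 7L, 7L, 7L),
  fr3_gap73 = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
)

#' Bundled example germline database
#'
#' A small IGHV reference database for examples, tests and simulations: the
#' nearest-reference alleles of six validated novel human IGHV alleles
#' ([example_novel_alleles()]), each with an IMGT position map so that
#' substitutions are named in IMGT coordinates.  With
#' `include_synthetic = TRUE` (the default) four clearly labelled synthetic
#' secondary alleles (`*90`/`*91` of the CNV-prone genes IGHV1-69 and
#' IGHV3-30; four planted substitutions each) are added so that multi-allele
#' copy-number scenarios can be simulated.
#'
#' @param include_synthetic Add the synthetic `*90`/`*91` secondary alleles.
#' @param include_novel Also append the six novel alleles themselves (used
#'   when a database containing the ground-truth novel sequences is needed,
#'   e.g. for genomic-DNA read filtering).
#' @return A [germline_db()].
#' @examples
#' db <- example_germline_db()
#' gene_index(db)
#' @export
example_germline_db <- function(include_synthetic = TRUE, include_novel = FALSE) {
  ex <- .ighv_examples
  maps <- lapply(seq_len(nrow(ex)), function(i) {
    imgt_position_map(nchar(ex$sequence[i]), ex$cdr1_len[i], ex$cdr2_len[i],
                      fr3_gap73 = ex$fr3_gap73[i])
  })
  # reconstruct each reference by restoring the named reference bases
  refs <- character(nrow(ex))
  for (i in seq_len(nrow(ex))) {
    parsed <- parse_novel_name(ex$name[i])
    subs <- parsed$substitutions
    subs$pos <- from_reported_pos(subs$pos, maps[[i]])
    refs[i] <- apply_substitutions(ex$sequence[i], invert_substitutions(subs))
  }
  base_names <- unname(vapply(ex$name, function(n) parse_novel_name(n)$base, ""))
  db <- germline_db(base_names, refs, position_map = maps)
  if (include_synthetic) {
    for (spec in list(list(base = "IGHV1-69*01", suffix = "*90", pos = c(30L, 75L, 120L, 250L)),
                      list(base = "IGHV1-69*01", suffix = "*91", pos = c(45L, 110L, 200L, 270L)),
                      list(base = "IGHV3-30*02", suffix = "*90", pos = c(30L, 75L, 120L, 250L)),
                      list(base = "IGHV3-30*02", suffix = "*91", pos = c(45L, 110L, 200L, 270L)))) {
      i <- match(spec$base, db$name)
      seq_i <- db$sequence[i]
      chars <- strsplit(seq_i, "")[[1]]
      ref_b <- chars[spec$pos]
      alt_b <- DNA_BASES[match(ref_b, DNA_BASES) %% 4L + 1L]
      syn <- apply_substitutions(seq_i, substitutions(ref_b, spec$pos, alt_b))
      row <- db[i, ]
      row$name <- paste0(allele_gene(spec$base), spec$suffix)
      row$sequence <- syn
      db <- validate_germline_db(dplyr::bind_rows(db, row))
    }
  }
  if (include_novel) {
    for (i in seq_len(nrow(ex))) {
      parsed <- parse_novel_name(ex$name[i])
      subs <- parsed$substitutions
      subs$pos <- from_reported_pos(subs$pos, maps[[i]])
      db <- add_novel_allele(db, parsed$base, subs)
    }
  }
  db
}

#' @rdname example_germline_db
#' @return `example_novel_alleles()` returns a tibble with the published
#'   name, base allele and full-length sequence of each bundled novel allele.
#' @export
example_novel_alleles <- function() {
  ex <- .ighv_examples
  tibble::tibble(
    name = ex$name,
    base_allele = unname(vapply(ex$name, function(n) parse_novel_name(n)$base, "")),
    sequence = ex$sequence
  )
}
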