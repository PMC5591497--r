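#' File-level prediction run
#'
#' Reads a repertoire and a germline FASTA, assigns, calls novel alleles,
#' and writes `assignments.tsv`, `calls.tsv`, `profiles.tsv`,
#' `novel_alleles.fasta` and a deterministic `manifest.json` (input
#' checksums, parameters, package version) into `out_dir`.  Outputs are
#' byte-identical across reruns with identical inputs and parameters.
#'
#' @param repertoire_path FASTA/FASTQ of unique IgM sequences (`;size=N`
#'   annotations honoured).
#' @param germline_path Germline allele FASTA (plain or IMGT-gapped).
#' @param out_dir Output directory, created if missing.
#' @param params [caller_params()].
#' @param collapse Collapse identical input sequences before assignment
#'   (disable when the input is already one record per unique molecule).
#' @param min_overlap Passed to [batch_assign()].
#' @return The [call_novel_alleles()] result, invisibly.
#' @export
run_predict <- function(repertoire_path, germline_path, out_dir,
                        params = caller_params(), collapse = TRUE,
                        min_overlap = 100L) {
  db <- parse_germline_fasta(germline_path)
  reads <- read_repertoire(repertoire_path)
  uniques <- if (collapse) collapse_unique(reads) else reads
  asn <- batch_assign(uniques, db, min_overlap = min_overlap)
  res <- call_novel_alleles(asn, db, params)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_assignments_tsv(asn, file.path(out_dir, "assignments.tsv"))
  readr::write_tsv(tidy.novel_call_set(res), file.path(out_dir, "calls.tsv"))
  profs <- dplyr::bind_rows(lapply(res$profiles, tibble::as_tibble))
  readr::write_tsv(profs, file.path(out_dir, "profiles.tsv"))
  if (nrow(res$calls) > 0L) {
    novel <- Biostrings::DNAStringSet(res$calls$novel_sequence)
    names(novel) <- res$calls$novel_name
    Biostrings::writeXStringSet(novel, file.path(out_dir, "novel_alleles.fasta"),
                                width = 80L)
  }
  write_manifest(out_dir,
                 inputs = c(repertoire = repertoire_path, germline = germline_path),
                 params = unclass(params),
                 extra = list(collapse = collapse, min_overlap = min_overlap))
  invisible(res)
}

#' File-level validation run
#'
#' Validates every candidate listed in a calls TSV (as written by
#' [run_predict()], or hand-written with at least a `novel_name` column)
#' against merged genomic-DNA amplicon reads, writing `validation.tsv` and a
#' run manifest.
#'
#' @param reads_path FASTA/FASTQ of merged amplicon reads.
#' @param germline_path Germline allele FASTA.
#' @param calls_path Calls TSV; candidates are resolved by `novel_name`.
#' @param out_dir Output directory.
#' @param params [validation_params()].
#' @param subject Subject identifier for the output rows.
#' @param gene_groups See [default_gene_groups()].
#' @return The validation tibble, invisibly.
#' @export
run_validate <- function(reads_path, germline_path, calls_path, out_dir,
                         params = validation_params(),
                         subject = NA_character_,
                         gene_groups = default_gene_groups()) {
  db <- parse_germline_fasta(germline_path)
  reads <- read_repertoire(reads_path)
  calls <- readr::read_tsv(calls_path, show_col_types = FALSE)
  if (!"novel_name" %in% names(calls)) {
    stop("calls TSV must have a novel_name column", call. = FALSE)
  }
  missing_base <- setdiff(
    vapply(calls$novel_name, function(n) parse_novel_name(n)$base, ""),
    db$name
  )
  if (length(missing_base) > 0L) {
    stop("candidate base allele(s) absent from the germline database: ",
         paste(missing_base, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::bind_rows(lapply(calls$novel_name, function(nm) {
    validate_candidate(reads, db, nm, params, gene_groups, subject = subject)
  }))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(out, file.path(out_dir, "validation.tsv"))
  write_manifest(out_dir,
                 inputs = c(reads = reads_path, germline = germline_path,
                            calls = calls_path),
                 params = unclass(params), extra = list(subject = subject))
  invisible(out)
}

#' File-level simulation run
#'
#' Simulates a genotype, its unique IgM repertoire and per-gene genomic-DNA
#' amplicon reads, writing `germline.fasta`, `repertoire.fasta`,
#' `gdna_<gene>.fastq`, truth tables and the full configuration used.
#'
#' @param genotype_spec Tibble (or TSV path) with `gene`, `copies`,
#'   optional `novel` columns; see [simulate_genotype()].
#' @param db A [germline_db()] (default: [example_germline_db()]).
#' @param out_dir Output directory.
#' @param params [sim_params()].
#' @param seed Integer seed; outputs are byte-identical per seed.
#' @return A list with `genotype`, `repertoire` and `gdna` (named list of
#'   read tibbles), invisibly.
#' @export
run_simulate <- function(genotype_spec, out_dir, db = example_germline_db(),
                         params = sim_params(), seed = 1L) {
  if (is.character(genotype_spec)) {
    genotype_spec <- readr::read_tsv(genotype_spec, show_col_types = FALSE)
  }
  gt <- simulate_genotype(db, genotype_spec, seed = seed)
  rep <- simulate_igm_repertoire(gt, params, seed = seed)
  genes <- unique(genotype_spec$gene)
  gdna <- lapply(seq_along(genes), function(k) {
    simulate_gdna_reads(gt, genes[k], params, seed = seed + k)
  })
  names(gdna) <- genes
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_germline_fasta(db, file.path(out_dir, "germline.fasta"))
  rep_set <- Biostrings::DNAStringSet(rep$sequence)
  names(rep_set) <- rep$id
  Biostrings::writeXStringSet(rep_set, file.path(out_dir, "repertoire.fasta"),
                              width = 80L)
  readr::write_tsv(rep[, setdiff(names(rep), "sequence")],
                   file.path(out_dir, "repertoire_truth.tsv"))
  for (g in genes) {
    reads <- gdna[[g]]
    if (nrow(reads) == 0L) next
    set <- Biostrings::DNAStringSet(reads$sequence)
    names(set) <- reads$id
    qual <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
    Biostrings::writeXStringSet(set, file.path(out_dir, paste0("gdna_", g, ".fastq")),
                                format = "fastq", qualities = qual)
    readr::write_tsv(reads[, setdiff(names(reads), "sequence")],
                     file.path(out_dir, paste0("gdna_", g, "_truth.tsv")))
  }
  readr::write_tsv(gt[, setdiff(names(gt), "sequence")],
                   file.path(out_dir, "genotype_truth.tsv"))
  write_manifest(out_dir, inputs = character(),
                 params = unclass(params), extra = list(seed = seed))
  invisible(list(genotype = gt, repertoire = rep, gdna = gdna))
}

#' @rdname build_concordance_table
#' @param predictions_path,validations_path,out_path TSV paths for the
#'   file-level form `run_report()`; predictions need `subject`,
#'   `candidate`, `predicted`; validations need `subject`, `candidate`,
#'   `status` (plus optional flags).
#' @export
run_report <- function(predictions_path, validations_path, out_path) {
  preds <- readr::read_tsv(predictions_path, show_col_types = FALSE)
  vals <- readr::read_tsv(validations_path, show_col_types = FALSE)
  tab <- build_concordance_table(preds, vals)
  readr::write_tsv(tibble::as_tibble(tab), out_path)
  invisible(tab)
}

write_assignments_tsv <- function(asn, path) {
  flat <- tibble::as_tibble(asn)
  flat$mismatches <- vapply(flat$mismatches, function(s) {
    paste(sub_tokens(s, check = FALSE), collapse = ",")
  }, "")
  flat$sequence <- NULL
  readr::write_tsv(flat, path)
}

write_manifest <- function(out_dir, inputs, params, extra = list()) {
  manifest <- list(
    tool = "igallele",
    version = as.character(utils::packageVersion("igallele")),
    inputs = as.list(if (length(inputs) > 0) tools::md5sum(inputs) else character()),
    params = params,
    extra = extra
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Flat key-value run configuration
#'
#' Reads `key = value` lines (comments with `#`); keys must belong to
#' [caller_params()], [validation_params()] or [sim_params()] — unknown keys
#' are rejected.  Command-line flags override file values.
#'
#' @param path Config file path.
#' @return Named list of parsed values (numerics converted).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  known <- unique(c(names(formals(caller_params)),
                    names(formals(validation_params)),
                    names(formals(sim_params)), "seed", "min_overlap"))
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", shQuote(ln), call. = FALSE)
    key <- trimws(kv[1])
    if (!key %in% known) stop("unknown config key: ", key, call. = FALSE)
    val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
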