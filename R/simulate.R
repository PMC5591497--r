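#' Simulation parameters
#'
#' The generator emulates the stated low-noise regime of unique IgM
#' sequences: each simulated sequence stands for one unique molecule drawn
#' from a diploid genotype copy, carrying independent per-position somatic
#' hypermutations (optionally boosted at hotspot positions) and per-base
#' sequencing errors.
#'
#' @param n_unique Number of unique sequences to emit.
#' @param shm_rate Per-position somatic hypermutation probability
#'   (default 0.005, the naive-enriched IgM regime).
#' @param hotspot_positions Ungapped positions with boosted mutation rate;
#'   off by default.
#' @param hotspot_multiplier Rate multiplier at hotspots (default 5).
#' @param seq_error_rate Per-base sequencing error probability
#'   (default 0.001).
#' @param gdna_depth Reads per genomic-DNA amplicon (default 500).
#' @param allele_usage Optional per-copy usage weights; default uniform over
#'   carried copies (so a gene's share is proportional to its copy number
#'   and a 1-of-4 novel copy is used by 25% of sequences).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_unique = 5000L, shm_rate = 0.005,
                       hotspot_positions = integer(), hotspot_multiplier = 5,
                       seq_error_rate = 0.001, gdna_depth = 500L,
                       allele_usage = NULL) {
  stopifnot(shm_rate >= 0, shm_rate <= 1, seq_error_rate >= 0,
            seq_error_rate <= 1, n_unique >= 1L, gdna_depth >= 1L,
            hotspot_multiplier >= 0)
  structure(list(n_unique = as.integer(n_unique), shm_rate = shm_rate,
                 hotspot_positions = as.integer(hotspot_positions),
                 hotspot_multiplier = hotspot_multiplier,
                 seq_error_rate = seq_error_rate,
                 gdna_depth = as.integer(gdna_depth),
                 allele_usage = allele_usage),
            class = "sim_params")
}

#' Simulate a diploid genotype with copy-number variation
#'
#' IGHV genes occur at 0-4 diploid copies through segmental duplication and
#' deletion; a genotype lists the allele sequence carried by each copy, with
#' novel alleles injected as substitutions on a database allele.
#'
#' @param db A [germline_db()].
#' @param genotype_spec Tibble with one row per gene: `gene`, `copies`
#'   (0-4), optional `alleles` (list column of allele names, recycled over
#'   copies; default: the gene's first allele), optional `novel` (a novel
#'   allele name such as `"IGHV1-8*02 (G234T)"`, or `NA`) replacing the last
#'   `novel_copies` copies (default 1; 2 of 2 models a homozygous novel
#'   genotype) with the constructed novel sequence.
#' @param seed Optional integer; the genotype construction is deterministic,
#'   the seed is only recorded.
#' @return A tibble of class `ig_genotype`: `gene`, `copy_id`,
#'   `allele_name`, `sequence`, `is_novel`, `base_allele`.
#' @examples
#' db <- example_germline_db()
#' gt <- simulate_genotype(db, tibble::tibble(
#'   gene = "IGHV1-8", copies = 2L, novel = "IGHV1-8*02 (G234T)"
#' ))
#' @export
simulate_genotype <- function(db, genotype_spec, seed = NULL) {
  stopifnot(inherits(db, "germline_db"), is.data.frame(genotype_spec))
  spec <- tibble::as_tibble(genotype_spec)
  if (!"novel" %in% names(spec)) spec$novel <- NA_character_
  if (!"novel_copies" %in% names(spec)) spec$novel_copies <- 1L
  if (any(spec$copies > 4L | spec$copies < 0L)) {
    stop("copies per gene must be within 0..4", call. = FALSE)
  }
  rows <- list()
  for (r in seq_len(nrow(spec))) {
    gene <- spec$gene[r]
    copies <- spec$copies[r]
    if (copies == 0L) next
    gene_alleles <- db$name[db$gene == gene & !db$is_novel]
    if (length(gene_alleles) == 0L) {
      stop("no alleles for gene ", gene, " in database", call. = FALSE)
    }
    alleles <- if ("alleles" %in% names(spec) && !is.null(spec$alleles[[r]])) {
      rep_len(spec$alleles[[r]], copies)
    } else {
      rep_len(gene_alleles[1], copies)
    }
    seqs <- db$sequence[match(alleles, db$name)]
    if (anyNA(seqs)) {
      stop("allele(s) not in database: ",
           paste(alleles[is.na(seqs)], collapse = ", "), call. = FALSE)
    }
    is_novel <- rep(FALSE, copies)
    base <- alleles
    if (!is.na(spec$novel[r])) {
      res <- resolve_novel_name(db, spec$novel[r])
      nk <- min(copies, max(1L, as.integer(spec$novel_copies[r])))
      which_novel <- seq.int(copies - nk + 1L, copies)
      seqs[which_novel] <- res$sequence
      alleles[which_novel] <- spec$novel[r]
      base[which_novel] <- res$base
      is_novel[which_novel] <- TRUE
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      gene = gene, copy_id = paste0(gene, ".c", seq_len(copies)),
      allele_name = alleles, sequence = seqs,
      is_novel = is_novel, base_allele = base
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(gene = character(), copy_id = character(),
                          allele_name = character(), sequence = character(),
                          is_novel = logical(), base_allele = character())
  }
  attr(out, "seed") <- seed
  class(out) <- c("ig_genotype", class(tibble::tibble()))
  out
}

# mutate equal-length sequences column-wise: per-position substitution with
# rate vector p (length L, recycled down columns), uniform choice among the
# three other bases
mutate_strings <- function(seqs, p) {
  n <- length(seqs)
  if (n == 0L) return(list(seqs = seqs, n_mut = integer()))
  L <- nchar(seqs[1])
  if (all(p == 0)) return(list(seqs = seqs, n_mut = integer(n)))
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = L)
  hit <- which(matrix(stats::runif(L * n) < p, nrow = L))
  if (length(hit) > 0L) {
    ref_idx <- match(chars[hit], DNA_BASES)
    alt_idx <- (ref_idx + sample.int(3L, length(hit), replace = TRUE) - 1L) %% 4L + 1L
    chars[hit] <- DNA_BASES[alt_idx]
  }
  n_mut <- tabulate((hit - 1L) %/% L + 1L, nbins = n)
  out <- seqs
  changed <- which(n_mut > 0L)
  for (i in changed) out[i] <- paste(chars[, i], collapse = "")
  list(seqs = out, n_mut = n_mut)
}

mutate_block <- function(source, n, p) {
  mutate_strings(rep(source, n), p)
}

#' Simulate a unique IgM repertoire from a genotype
#'
#' Each unique sequence is drawn from a genotype copy (uniformly, or per
#' `allele_usage` weights), somatically hypermutated position-by-position at
#' `shm_rate` (hotspots multiplied), then subjected to per-base sequencing
#' error.  With one of a gene's four copies novel, the expected fraction of
#' that gene's sequences carrying the novel pattern is 25%.
#'
#' @param genotype An [simulate_genotype()] result with at least one copy.
#' @param params [sim_params()].
#' @param seed Integer seed; the output is reproducible bit-for-bit.
#' @return A tibble usable directly as [batch_assign()] input: `id`,
#'   `sequence`, `multiplicity` (always 1), plus truth columns `gene`,
#'   `copy_id`, `allele_name`, `is_novel`, `n_shm`, `n_err`.
#' @export
simulate_igm_repertoire <- function(genotype, params = sim_params(), seed = 1L) {
  if (nrow(genotype) == 0L) {
    stop("all-zero-copy genotype: nothing to express", call. = FALSE)
  }
  n <- params$n_unique
  usage <- params$allele_usage
  if (is.null(usage)) usage <- rep(1, nrow(genotype))
  stopifnot(length(usage) == nrow(genotype))
  withr::with_seed(seed, {
    copy_of <- sample.int(nrow(genotype), n, replace = TRUE, prob = usage)
    seqs <- character(n)
    n_shm <- integer(n)
    n_err <- integer(n)
    for (ci in unique(copy_of)) {
      idx <- which(copy_of == ci)
      src <- genotype$sequence[ci]
      L <- nchar(src)
      p_shm <- rep(params$shm_rate, L)
      hs <- params$hotspot_positions[params$hotspot_positions <= L]
      p_shm[hs] <- pmin(1, p_shm[hs] * params$hotspot_multiplier)
      shm <- mutate_block(src, length(idx), p_shm)
      n_shm[idx] <- shm$n_mut
      err <- mutate_strings(shm$seqs, rep(params$seq_error_rate, L))
      n_err[idx] <- err$n_mut
      seqs[idx] <- err$seqs
    }
    tibble::tibble(
      id = sprintf("s%06d", seq_len(n)),
      sequence = seqs,
      multiplicity = 1L,
      gene = genotype$gene[copy_of],
      copy_id = genotype$copy_id[copy_of],
      allele_name = genotype$allele_name[copy_of],
      is_novel = genotype$is_novel[copy_of],
      n_shm = n_shm,
      n_err = n_err
    )
  })
}

#' Simulate genomic-DNA amplicon reads for one gene
#'
#' Reads are drawn uniformly from the gene's carried copies with per-base
#' sequencing error and *no* somatic hypermutation: genomic DNA from
#' FACS-sorted non-B cells carries the unrecombined germline sequence.
#'
#' @param genotype An [simulate_genotype()] result.
#' @param gene Gene to amplify.
#' @param params [sim_params()] (`gdna_depth` and `seq_error_rate` apply).
#' @param seed Integer seed.
#' @param amplicon Optional `c(start, end)` in ungapped allele coordinates;
#'   default the full allele span of each copy.
#' @return A tibble `id`, `sequence`, `gene`, `copy_id`, `allele_name`,
#'   `is_novel`; zero rows with attribute `deletion = TRUE` when the gene is
#'   absent from the genotype.
#' @export
simulate_gdna_reads <- function(genotype, gene, params = sim_params(),
                                seed = 1L, amplicon = NULL) {
  copies <- genotype[genotype$gene == gene, , drop = FALSE]
  if (nrow(copies) == 0L) {
    out <- tibble::tibble(id = character(), sequence = character(),
                          gene = character(), copy_id = character(),
                          allele_name = character(), is_novel = logical())
    attr(out, "deletion") <- TRUE
    return(out)
  }
  n <- params$gdna_depth
  withr::with_seed(seed + 1000003L, {
    copy_of <- sample.int(nrow(copies), n, replace = TRUE)
    seqs <- character(n)
    for (ci in unique(copy_of)) {
      idx <- which(copy_of == ci)
      src <- copies$sequence[ci]
      if (!is.null(amplicon)) {
        src <- substr(src, amplicon[1], min(amplicon[2], nchar(src)))
      }
      blk <- mutate_block(src, length(idx), rep(params$seq_error_rate, nchar(src)))
      seqs[idx] <- blk$seqs
    }
    out <- tibble::tibble(
      id = sprintf("g%06d", seq_len(n)),
      sequence = seqs,
      gene = gene,
      copy_id = copies$copy_id[copy_of],
      allele_name = copies$allele_name[copy_of],
      is_novel = copies$is_novel[copy_of]
    )
    attr(out, "deletion") <- FALSE
    out
  })
}
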