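#' Collapse reads to unique sequences
#'
#' Exact deduplication after uppercasing: one record per distinct string,
#' with multiplicities summing to the input read count.  Ordering is
#' deterministic: multiplicity descending, then sequence lexicographic.
#'
#' @param reads Character vector of DNA strings, or a data frame with a
#'   `sequence` column (an optional `multiplicity` column is honoured, as
#'   produced by `;size=N`-annotated FASTA input).
#' @return A tibble with columns `id`, `sequence`, `multiplicity`.
#' @examples
#' collapse_unique(c("ACGT", "ACGT", "ACGA"))
#' @export
collapse_unique <- function(reads) {
  if (is.data.frame(reads)) {
    mult <- if ("multiplicity" %in% names(reads)) reads$multiplicity else rep(1L, nrow(reads))
    reads_chr <- reads$sequence
  } else {
    reads_chr <- as.character(reads)
    mult <- rep(1L, length(reads_chr))
  }
  if (length(reads_chr) == 0L) stop("no input reads", call. = FALSE)
  reads_chr <- toupper(reads_chr)
  agg <- rowsum(mult, group = reads_chr)
  out <- tibble::tibble(sequence = rownames(agg), multiplicity = as.integer(agg[, 1]))
  out <- out[order(-out$multiplicity, out$sequence, method = "radix"), ]
  out$id <- sprintf("u%05d", seq_len(nrow(out)))
  out[, c("id", "sequence", "multiplicity")]
}

#' Read repertoire or amplicon sequences
#'
#' Reads FASTA or FASTQ (qualities are ignored); `;size=N` multiplicity
#' annotations on the identifiers are honoured for pre-collapsed input.
#'
#' @param path Input file; FASTQ is recognised by a `.fastq`/`.fq` suffix.
#' @return A tibble with columns `id`, `sequence`, `multiplicity`.
#' @export
read_repertoire <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)) "fastq" else "fasta"
  set <- Biostrings::readDNAStringSet(path, format = fmt)
  if (length(set) == 0L) stop("empty input: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  size <- suppressWarnings(as.integer(sub("^.*;size=(\\d+).*$", "\\1", ids)))
  size[is.na(size)] <- 1L
  tibble::tibble(id = sub(";size=\\d+;?", "", ids),
                 sequence = toupper(as.character(set)),
                 multiplicity = size)
}

# ---- core assignment engine ------------------------------------------------
#
# Queries are anchored on each allele by exact k-mer seeds (three seeds
# spread over the 5' half of the query, located by hashing the allele's
# k-mers), then scored by Hamming distance over the anchored overlap, with
# free ends: a query may run past the allele 3' end (CDR3/junction overhang)
# or start ahead of it; the overhang is ignored.  Queries that no seed can
# anchor, or whose best anchored distance is suspiciously large, are
# re-examined with a gapped overlap alignment (Biostrings) to detect indels.
# The best allele maximises matched bases over the aligned interval, which
# for equal-length intervals is the minimum-mismatch allele and across
# truncated shadows prefers the longer interval; remaining ties go to the
# lexicographically smallest allele name.

.assign_core <- function(seqs, db, min_overlap = 100L, seed_len = 24L) {
  n <- length(seqs)
  allele_order <- order(db$name, method = "radix")
  anames <- db$name[allele_order]
  aseqs <- db$sequence[allele_order]
  alens <- nchar(aseqs)
  araw <- lapply(aseqs, charToRaw)
  kmer_tables <- lapply(aseqs, function(s) {
    L <- nchar(s)
    if (L < seed_len) return(character())
    substring(s, 1:(L - seed_len + 1L), seed_len:L)
  })

  lens <- nchar(seqs)
  seed_pos <- c(1L, 31L, 61L, 91L, 121L)
  seed_mat <- vapply(seed_pos, function(p) {
    out <- rep(NA_character_, n)
    ok <- lens >= p + seed_len - 1L
    out[ok] <- substring(seqs[ok], p, p + seed_len - 1L)
    out
  }, character(n))
  if (n == 1L) seed_mat <- matrix(seed_mat, nrow = 1L)

  offsets <- matrix(NA_integer_, nrow = n, ncol = length(anames))
  for (j in seq_along(anames)) {
    off <- rep(NA_integer_, n)
    for (k in seq_along(seed_pos)) {
      need <- is.na(off) & !is.na(seed_mat[, k])
      if (!any(need)) next
      hit <- match(seed_mat[need, k], kmer_tables[[j]])
      off[need] <- hit - (seed_pos[k] - 1L)
    }
    offsets[, j] <- off
  }
  # alleles left unanchored borrow the query's consensus offset: V alleles
  # share a common 5' frame, so the anchor found on one allele nearly always
  # holds on the others
  row_med <- apply(offsets, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) NA_integer_ else as.integer(round(stats::median(x)))
  })
  for (j in seq_along(anames)) {
    na_j <- is.na(offsets[, j])
    offsets[na_j, j] <- row_med[na_j]
  }

  best_score <- rep(-Inf, n)
  best_ov <- integer(n)
  best_mm <- rep(NA_integer_, n)
  best_j <- rep(NA_integer_, n)
  best_off <- rep(NA_integer_, n)
  for (L in unique(lens)) {
    idxL <- which(lens == L)
    M <- matrix(charToRaw(paste(seqs[idxL], collapse = "")), nrow = L)
    for (j in seq_along(anames)) {
      offs <- offsets[idxL, j]
      for (o in unique(offs[!is.na(offs)])) {
        a_start <- max(1L, o)
        a_end <- min(alens[j], o + L - 1L)
        ov <- a_end - a_start + 1L
        if (ov < min_overlap) next
        sel <- which(offs == o)
        qs <- (a_start - o + 1L):(a_end - o + 1L)
        mm <- as.integer(colSums(M[qs, sel, drop = FALSE] != araw[[j]][a_start:a_end]))
        sc <- ov - mm
        gi <- idxL[sel]
        upd <- sc > best_score[gi] | (sc == best_score[gi] & ov > best_ov[gi])
        if (any(upd)) {
          g <- gi[upd]
          best_score[g] <- sc[upd]
          best_ov[g] <- ov
          best_mm[g] <- mm[upd]
          best_j[g] <- j
          best_off[g] <- o
        }
      }
    }
  }

  allele_v <- anames[best_j]
  start_v <- pmax(1L, best_off)
  qstart_v <- start_v - best_off + 1L
  end_v <- pmin(alens[best_j], best_off + lens - 1L)
  mm_v <- best_mm
  indel_v <- rep(FALSE, n)
  status_v <- ifelse(is.na(best_j), "unassignable", "assigned")
  mism_list <- rep(list(fast_subs(character(), integer(), character())), n)

  # mismatch lists for anchored assignments, batched per (length, allele,
  # offset) group on the same raw matrices used for scoring
  for (L in unique(lens)) {
    idxL <- which(lens == L & !is.na(best_j) & best_mm > 0L)
    if (length(idxL) == 0L) next
    M <- matrix(charToRaw(paste(seqs[idxL], collapse = "")), nrow = L)
    key <- paste(best_j[idxL], best_off[idxL])
    for (grp in split(seq_along(idxL), key)) {
      i1 <- idxL[grp[1]]
      j <- best_j[i1]
      o <- best_off[i1]
      a_pos <- start_v[i1]:end_v[i1]
      qs <- a_pos - o + 1L
      ar <- araw[[j]][a_pos]
      D <- M[qs, grp, drop = FALSE] != ar
      hits <- which(D, arr.ind = TRUE)
      if (nrow(hits) == 0L) next
      alt_all <- rawToChar(M[qs, grp, drop = FALSE][D], multiple = TRUE)
      ref_all <- rawToChar(ar[hits[, 1L]], multiple = TRUE)
      pos_all <- a_pos[hits[, 1L]]
      for (piece in split(seq_len(nrow(hits)), hits[, 2L])) {
        i <- idxL[grp[as.integer(hits[piece[1], 2L])]]
        ord <- piece[order(pos_all[piece])]
        mism_list[[i]] <- fast_subs(ref_all[ord], pos_all[ord], alt_all[ord])
      }
    }
  }

  # gapped re-examination: unanchored queries and suspiciously distant hits
  suspicious <- which(is.na(best_j) |
                        best_mm > pmax(8L, ceiling(0.05 * best_ov)))
  for (i in suspicious) {
    aln <- .gapped_fallback(seqs[i], anames, aseqs, min_overlap)
    if (is.null(aln)) {
      if (is.na(best_j[i])) status_v[i] <- "unassignable"
      next
    }
    anchored_matches <- if (is.na(best_j[i])) -Inf else best_score[i]
    if (aln$matches > anchored_matches) {
      allele_v[i] <- aln$allele
      start_v[i] <- aln$start
      end_v[i] <- aln$end
      qstart_v[i] <- aln$query_start
      mm_v[i] <- aln$mismatches
      if (aln$indels > 0L) {
        indel_v[i] <- TRUE
        status_v[i] <- "indel"
        mism_list[[i]] <- fast_subs(character(), integer(), character())
        mm_v[i] <- NA_integer_
      } else {
        status_v[i] <- "assigned"
        mism_list[[i]] <- aln$mismatch_table
      }
    }
  }
  tibble::new_tibble(list(
    allele = allele_v, aligned_start = start_v, aligned_end = end_v,
    query_start = qstart_v, n_mismatches = mm_v, mismatches = mism_list,
    has_indel = indel_v, status = status_v
  ), nrow = n)
}

# no-validation substitution constructor for hot inner loops; inputs are
# already ordered and legal by construction
fast_subs <- function(ref, pos, alt) {
  tibble::new_tibble(list(ref = ref, pos = as.integer(pos), alt = alt),
                     nrow = length(pos))
}

.gapped_fallback <- function(seq, anames, aseqs, min_overlap) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  best <- NULL
  for (j in seq_along(anames)) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = seq, subject = aseqs[j], type = "overlap",
      substitutionMatrix = mat, gapOpening = 4, gapExtension = 1
    )
    s <- Biostrings::subject(aln)
    ov <- Biostrings::end(s) - Biostrings::start(s) + 1L
    if (ov < min_overlap) next
    nm <- Biostrings::nmatch(aln)
    cand <- list(
      allele = anames[j],
      start = Biostrings::start(s), end = Biostrings::end(s),
      query_start = Biostrings::start(Biostrings::pattern(aln)),
      matches = nm, mismatches = Biostrings::nmismatch(aln),
      indels = sum(Biostrings::nindel(aln)@insertion[, "Length"]) +
        sum(Biostrings::nindel(aln)@deletion[, "Length"]),
      overlap = ov, aln = aln
    )
    if (is.null(best) || cand$matches > best$matches ||
        (cand$matches == best$matches && cand$overlap > best$overlap)) {
      best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  if (best$indels == 0L) {
    mt <- Biostrings::mismatchTable(best$aln)
    best$mismatch_table <- substitutions(
      ref = as.character(mt$SubjectSubstring),
      pos = mt$SubjectStart,
      alt = as.character(mt$PatternSubstring)
    )
  }
  best$aln <- NULL
  best
}

#' Assign unique sequences to best-matched germline alleles
#'
#' Each query is aligned against every allele of `db` (free end gaps, so a
#' query may overhang the allele 3' end into the junction) and assigned to
#' the allele maximising matched bases over the aligned germline interval —
#' for equal-length intervals the minimum-mismatch allele, with ties broken
#' towards the longer aligned interval (so a full-length allele beats a
#' truncated shadow of itself) and then the lexicographically smallest
#' allele name.  Mismatches are recorded as substitutions in ungapped
#' germline coordinates.  Queries whose best alignment contains an indel are
#' flagged (`status = "indel"`) and carry no mismatch list; queries that no
#' allele covers with at least `min_overlap` nt are `"unassignable"`.
#'
#' @param uniques A tibble from [collapse_unique()]/[read_repertoire()] (or
#'   a character vector of sequences).
#' @param db A [germline_db()].
#' @param min_overlap Minimum aligned germline interval, nt.
#' @return A tibble of class `ig_assignments`: one row per query with
#'   `query_id`, `sequence`, `multiplicity`, `allele`, `aligned_start`,
#'   `aligned_end`, `query_start` (query position aligned to
#'   `aligned_start`), `n_mismatches`, `mismatches` (list column),
#'   `has_indel`, `status`.
#' @export
batch_assign <- function(uniques, db, min_overlap = 100L) {
  stopifnot(inherits(db, "germline_db"))
  if (is.character(uniques)) {
    uniques <- tibble::tibble(id = sprintf("q%05d", seq_along(uniques)),
                              sequence = uniques,
                              multiplicity = 1L)
  }
  if (nrow(uniques) == 0L) stop("no query sequences", call. = FALSE)
  seqs <- toupper(uniques$sequence)
  invalid <- grepl("[^ACGT]", seqs)
  if (any(invalid)) {
    n <- length(seqs)
    res <- tibble::tibble(
      allele = NA_character_, aligned_start = NA_integer_, aligned_end = NA_integer_,
      query_start = NA_integer_, n_mismatches = NA_integer_,
      mismatches = rep(list(substitutions()), n),
      has_indel = FALSE, status = "invalid", .rows = n
    )
    if (any(!invalid)) {
      core <- .assign_core(seqs[!invalid], db, min_overlap = min_overlap)
      for (col in names(core)) res[[col]][!invalid] <- core[[col]]
    }
  } else {
    res <- .assign_core(seqs, db, min_overlap = min_overlap)
  }
  out <- tibble::tibble(
    query_id = uniques$id,
    sequence = seqs,
    multiplicity = if ("multiplicity" %in% names(uniques)) uniques$multiplicity else 1L
  )
  out <- dplyr::bind_cols(out, res)
  class(out) <- c("ig_assignments", class(out))
  out
}

#' @rdname batch_assign
#' @param query A single sequence (string or one-row tibble).
#' @details `assign_best_allele()` is the single-query form; it errors on
#'   non-A/C/G/T queries and on queries no allele covers (`"unassignable"`).
#' @export
assign_best_allele <- function(query, db, min_overlap = 100L) {
  if (is.data.frame(query)) query <- query$sequence
  stopifnot(length(query) == 1L)
  if (grepl("[^ACGTacgt]", query)) {
    stop("query contains non-A/C/G/T characters", call. = FALSE)
  }
  res <- batch_assign(query, db, min_overlap = min_overlap)
  if (res$status == "unassignable") {
    stop("unassignable: no allele reaches the minimum overlap of ",
         min_overlap, " nt", call. = FALSE)
  }
  res
}

#' Summarise an assignment table
#'
#' @param x An `ig_assignments` tibble.
#' @param ... Unused.
#' @return One row with counts per status and per-allele group sizes
#'   available via `dplyr::count(x, allele)`.
#' @method glance ig_assignments
#' @export
glance.ig_assignments <- function(x, ...) {
  tibble::tibble(
    n_queries = nrow(x),
    n_assigned = sum(x$status == "assigned"),
    n_indel = sum(x$status == "indel"),
    n_unassignable = sum(x$status == "unassignable"),
    n_invalid = sum(x$status == "invalid"),
    n_alleles = length(unique(x$allele[x$status == "assigned"]))
  )
}
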