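#' Germline V-allele databases
#'
#' A germline database is a tibble with one row per allele and columns:
#' `name` (e.g. `"IGHV1-8*02"`), `gene` (`"IGHV1-8"`), `family` (`"IGHV1"`),
#' `sequence` (ungapped uppercase DNA), `position_map` (list column; integer
#' map from ungapped index to reported coordinate, or `NULL` for identity —
#' see [imgt_position_map()]), `is_novel`, `base_allele` and `substitutions`
#' (list column of substitution tibbles, ungapped coordinates).
#'
#' @param name Character vector of allele names (`GENE*NN`, optionally with
#'   a novel-allele parenthetical).
#' @param sequence Ungapped DNA strings (same length as `name`).
#' @param position_map Optional list of integer maps (or `NULL`s).
#' @param is_novel,base_allele,substitutions Novel-allele bookkeeping;
#'   usually filled by [add_novel_allele()] rather than by hand.
#' @return A `germline_db` tibble.
#' @export
germline_db <- function(name, sequence, position_map = NULL,
                        is_novel = FALSE, base_allele = NA_character_,
                        substitutions = NULL) {
  n <- length(name)
  stopifnot(length(sequence) == n)
  if (is.null(position_map)) position_map <- rep(list(NULL), n)
  if (is.null(substitutions)) substitutions <- rep(list(NULL), n)
  sequence <- toupper(sequence)
  base <- unname(vapply(name, function(x) parse_allele_token(x)$allele, ""))
  db <- tibble::tibble(
    name = as.character(name),
    gene = unname(vapply(base, allele_gene, "")),
    family = unname(vapply(base, allele_family, "")),
    sequence = sequence,
    position_map = position_map,
    is_novel = rep_len(is_novel, n),
    base_allele = rep_len(base_allele, n),
    substitutions = substitutions
  )
  validate_germline_db(db)
}

validate_germline_db <- function(db) {
  if (nrow(db) == 0L) stop("germline database is empty", call. = FALSE)
  if (anyDuplicated(db$name)) {
    stop("duplicate allele name(s): ",
         paste(unique(db$name[duplicated(db$name)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- grepl("[^ACGT]", db$sequence)
  if (any(bad)) {
    stop("allele sequence(s) with non-A/C/G/T characters (ambiguity codes are ",
         "not allowed): ", paste(db$name[bad], collapse = ", "), call. = FALSE)
  }
  ok_map <- vapply(seq_len(nrow(db)), function(i) {
    m <- db$position_map[[i]]
    is.null(m) || length(m) == nchar(db$sequence[i])
  }, TRUE)
  if (!all(ok_map)) {
    stop("position map length disagrees with sequence length for: ",
         paste(db$name[!ok_map], collapse = ", "), call. = FALSE)
  }
  class(db) <- c("germline_db", class(tibble::tibble()))
  db
}

# ---- allele name parsing ---------------------------------------------------

ALLELE_TOKEN_RE <- "[A-Za-z][A-Za-z0-9/.-]*\\*[0-9]+"

parse_allele_token <- function(name) {
  # split a possibly-novel name into the base allele token and its
  # substitution clause; "IGHV1-8*02 (G234T)" -> base + tokens
  m <- regexec(paste0("^(", ALLELE_TOKEN_RE, ")(?: \\(([^)]+)\\))?$"), name)
  hit <- regmatches(name, m)[[1]]
  if (length(hit) == 0L) {
    stop("cannot parse allele name: ", shQuote(name), call. = FALSE)
  }
  list(allele = hit[2], subs = if (nzchar(hit[3])) hit[3] else NULL)
}

allele_gene <- function(allele) sub("\\*.*$", "", allele)

allele_family <- function(allele) {
  fam <- regmatches(allele, regexpr("^[A-Za-z]+[0-9]+", allele))
  if (length(fam) == 0L) allele_gene(allele) else fam
}

#' Name a novel allele
#'
#' Novel alleles are named by their nearest reference allele followed by the
#' substitution tokens in parentheses, underscore-joined:
#' `IGHV1-8*02 (G234T)`, `IGHV4-61*01 (C93T_C136G_A138C)`.  When the base
#' allele carries a position map (IMGT numbering), substitution positions are
#' reported in map coordinates; pass `map = NULL` for raw ungapped positions.
#'
#' @param base Base allele name.
#' @param subs Substitution tibble in ungapped base-allele coordinates.
#' @param map Optional position map of the base allele (see
#'   [imgt_position_map()]).
#' @return The canonical novel-allele name, a string.
#' @examples
#' name_novel_allele("IGHV1-8*02", substitutions("G", 234, "T"))
#' @export
name_novel_allele <- function(base, subs, map = NULL) {
  subs <- validate_substitutions(subs)
  if (nrow(subs) == 0L) {
    stop("a novel allele must differ from its base: empty substitution set",
         call. = FALSE)
  }
  labelled <- subs
  labelled$pos <- to_reported_pos(subs$pos, map)
  paste0(base, " (", paste(sub_tokens(labelled, check = FALSE), collapse = "_"), ")")
}

#' Parse a novel-allele name
#'
#' Inverse of [name_novel_allele()]: splits a canonical novel-allele name
#' into its base allele and substitution set.  Positions are returned in the
#' coordinate frame the name was written in (IMGT numbering for published
#' names); use [resolve_novel_name()] to obtain ungapped positions against a
#' database.
#'
#' @param name A novel-allele name.
#' @return A list with elements `base` (string) and `substitutions` (tibble).
#' @examples
#' parse_novel_name("IGHV4-61*01 (C93T_C136G_A138C)")
#' @export
parse_novel_name <- function(name) {
  parts <- parse_allele_token(name)
  if (is.null(parts$subs)) {
    stop(shQuote(name), " is not a novel-allele name (no substitution clause)",
         call. = FALSE)
  }
  list(base = parts$allele, substitutions = parse_sub_tokens(parts$subs))
}

#' @rdname parse_novel_name
#' @param db A [germline_db()] containing the base allele.
#' @return `resolve_novel_name()` additionally converts positions to ungapped
#'   base-allele coordinates and returns the constructed novel sequence.
#' @export
resolve_novel_name <- function(db, name) {
  parsed <- parse_novel_name(name)
  i <- match(parsed$base, db$name)
  if (is.na(i)) {
    stop("base allele ", parsed$base, " not found in the database", call. = FALSE)
  }
  map <- db$position_map[[i]]
  subs <- parsed$substitutions
  subs$pos <- from_reported_pos(subs$pos, map)
  subs <- validate_substitutions(subs)
  list(
    base = parsed$base,
    substitutions = subs,
    sequence = apply_substitutions(db$sequence[i], subs)
  )
}

#' Add a novel allele to a database
#'
#' Constructs the novel sequence from its base allele plus substitutions,
#' names it canonically, and appends it.  The novel allele inherits the base
#' allele's position map.
#'
#' @param db A [germline_db()].
#' @param base Base allele name, present in `db`.
#' @param subs Substitution tibble in ungapped base-allele coordinates, or a
#'   token string / full novel name (label coordinates) to be resolved.
#' @return The extended database.
#' @export
add_novel_allele <- function(db, base, subs) {
  if (is.character(subs)) {
    nm <- if (grepl("(", subs, fixed = TRUE)) subs else paste0(base, " (", subs, ")")
    res <- resolve_novel_name(db, nm)
    base <- res$base
    subs <- res$substitutions
  }
  i <- match(base, db$name)
  if (is.na(i)) stop("base allele ", base, " not found", call. = FALSE)
  subs <- validate_substitutions(subs)
  map <- db$position_map[[i]]
  name <- name_novel_allele(base, subs, map)
  if (name %in% db$name) return(db)
  row <- tibble::tibble(
    name = name,
    gene = db$gene[i],
    family = db$family[i],
    sequence = apply_substitutions(db$sequence[i], subs),
    position_map = list(map),
    is_novel = TRUE,
    base_allele = base,
    substitutions = list(subs)
  )
  validate_germline_db(dplyr::bind_rows(db, row))
}

# ---- FASTA I/O -------------------------------------------------------------

#' Read a germline allele FASTA
#'
#' Accepts plain headers (`>IGHV1-8*02`), IMGT pipe-delimited headers (the
#' allele token in the second field), and novel-allele headers written by
#' [write_germline_fasta()].  IMGT gap characters (`.`) are stripped; when
#' present, the gapped layout is retained as the allele's position map so
#' substitutions are reported in IMGT coordinates.
#'
#' @param path FASTA file path.
#' @return A [germline_db()].
#' @export
parse_germline_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  headers <- names(set)
  raw_seqs <- toupper(as.character(set))
  names(raw_seqs) <- NULL
  alleles <- vapply(headers, extract_allele_name, "")
  maps <- vector("list", length(raw_seqs))
  seqs <- character(length(raw_seqs))
  for (i in seq_along(raw_seqs)) {
    s <- raw_seqs[i]
    if (grepl(".", s, fixed = TRUE)) {
      maps[[i]] <- position_map_from_gapped(s)
      s <- gsub(".", "", s, fixed = TRUE)
    }
    seqs[i] <- s
  }
  db <- germline_db(alleles, seqs, position_map = maps)
  # fill in novel-allele bookkeeping for any novel-named records
  for (i in which(grepl(" (", db$name, fixed = TRUE))) {
    parsed <- parse_novel_name(db$name[i])
    db$is_novel[i] <- TRUE
    db$base_allele[i] <- parsed$base
    j <- match(parsed$base, db$name)
    if (!is.na(j)) {
      subs <- parsed$substitutions
      subs$pos <- from_reported_pos(subs$pos, db$position_map[[j]])
      db$substitutions[[i]] <- validate_substitutions(subs)
    }
  }
  db
}

extract_allele_name <- function(header) {
  header <- trimws(header)
  fields <- strsplit(header, "|", fixed = TRUE)[[1]]
  candidate <- if (length(fields) >= 2L) trimws(fields[2]) else header
  m <- regmatches(candidate, regexpr(paste0("^", ALLELE_TOKEN_RE, "(?: \\([^)]+\\))?"),
                                     candidate))
  if (length(m) == 0L) {
    # fall back to searching the whole header
    m <- regmatches(header, regexpr(ALLELE_TOKEN_RE, header))
  }
  if (length(m) == 0L) {
    stop("no parseable allele token in FASTA header: ", shQuote(header),
         call. = FALSE)
  }
  m
}

#' @rdname parse_germline_fasta
#' @param db A [germline_db()].
#' @param path Output path.
#' @details `write_germline_fasta()` writes the allele name as the full
#'   header; alleles carrying a position map are written IMGT-gapped (`.` at
#'   the gap positions) so that write-then-parse round-trips names,
#'   sequences *and* coordinate maps bit-exactly.
#' @export
write_germline_fasta <- function(db, path) {
  stopifnot(inherits(db, "germline_db"))
  out <- vapply(seq_len(nrow(db)), function(i) {
    m <- db$position_map[[i]]
    if (is.null(m)) return(db$sequence[i])
    chars <- rep(".", max(m))
    chars[m] <- strsplit(db$sequence[i], "")[[1]]
    paste(chars, collapse = "")
  }, "")
  set <- Biostrings::DNAStringSet(out)
  names(set) <- db$name
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' @rdname germline_db
#' @param db A [germline_db()].
#' @return `gene_index()` returns a tibble mapping `gene` to its allele
#'   names.
#' @export
gene_index <- function(db) {
  stopifnot(inherits(db, "germline_db"))
  out <- dplyr::summarise(dplyr::group_by(db, .data$gene),
                          alleles = list(.data$name), .groups = "drop")
  tibble::as_tibble(out)
}

#' @export
print.germline_db <- function(x, ...) {
  cat("<germline_db> ", nrow(x), " alleles, ", length(unique(x$gene)),
      " genes (", sum(x$is_novel), " novel)\n", sep = "")
  NextMethod()
}
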