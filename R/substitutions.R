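#' Substitution tables
#'
#' A substitution records a single-nucleotide difference to a germline
#' reference sequence: the reference base, its 1-based position in the
#' ungapped reference, and the alternate base.  Substitution sets are plain
#' tibbles with columns `ref`, `pos`, `alt`, kept sorted by position, and are
#' rendered as `<ref><pos><alt>` tokens (e.g. `"G234T"`) joined by
#' underscores in allele names.
#'
#' @param ref,alt Character vectors of single bases in `A`, `C`, `G`, `T`.
#' @param pos Integer vector of 1-based positions; pairwise distinct.
#'
#' @return A tibble with columns `ref` (character), `pos` (integer) and
#'   `alt` (character), sorted by `pos`.
#'
#' @examples
#' substitutions("G", 234, "T")
#' sub_tokens(substitutions(c("C", "C", "A"), c(93, 136, 138), c("T", "G", "C")))
#' @export
substitutions <- function(ref = character(), pos = integer(), alt = character()) {
  tbl <- tibble::tibble(
    ref = toupper(as.character(ref)),
    pos = as.integer(pos),
    alt = toupper(as.character(alt))
  )
  validate_substitutions(tbl)
}

validate_substitutions <- function(tbl) {
  stopifnot(is.data.frame(tbl), all(c("ref", "pos", "alt") %in% names(tbl)))
  bad_base <- !tbl$ref %in% DNA_BASES | !tbl$alt %in% DNA_BASES
  if (any(bad_base)) {
    stop("substitution bases must be one of A/C/G/T: ",
         paste(sub_tokens(tbl[bad_base, ], check = FALSE), collapse = ", "),
         call. = FALSE)
  }
  if (any(tbl$ref == tbl$alt)) {
    stop("substitution with identical reference and alternate base: ",
         paste(sub_tokens(tbl[tbl$ref == tbl$alt, ], check = FALSE), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(tbl$pos)) || any(tbl$pos < 1L)) {
    stop("substitution positions must be integers >= 1", call. = FALSE)
  }
  if (anyDuplicated(tbl$pos)) {
    stop("substitution positions must be pairwise distinct: position ",
         paste(unique(tbl$pos[duplicated(tbl$pos)]), collapse = ", "),
         call. = FALSE)
  }
  tbl[order(tbl$pos), c("ref", "pos", "alt")]
}

DNA_BASES <- c("A", "C", "G", "T")

#' @rdname substitutions
#' @param subs A substitution tibble.
#' @param check Validate `subs` before formatting.
#' @export
sub_tokens <- function(subs, check = TRUE) {
  if (check) subs <- validate_substitutions(subs)
  paste0(subs$ref, subs$pos, subs$alt)
}

#' @rdname substitutions
#' @param tokens Character vector of `<ref><pos><alt>` tokens, or a single
#'   underscore-joined string such as `"C93T_C136G_A138C"`.
#' @export
parse_sub_tokens <- function(tokens) {
  if (length(tokens) == 1L && grepl("_", tokens, fixed = TRUE)) {
    tokens <- strsplit(tokens, "_", fixed = TRUE)[[1]]
  }
  m <- regmatches(tokens, regexec("^([ACGTacgt])([0-9]+)([ACGTacgt])$", tokens))
  bad <- lengths(m) != 4L
  if (any(bad)) {
    stop("malformed substitution token(s): ",
         paste(shQuote(tokens[bad]), collapse = ", "), call. = FALSE)
  }
  substitutions(
    ref = vapply(m, `[`, "", 2L),
    pos = as.integer(vapply(m, `[`, "", 3L)),
    alt = vapply(m, `[`, "", 4L)
  )
}

#' Apply substitutions to a sequence
#'
#' Installs the alternate base of each substitution into `sequence`,
#' checking first that the reference base is present at every position.
#' Positions index the ungapped sequence, 1-based.
#'
#' @param sequence A single DNA string.
#' @param subs Substitution tibble (see [substitutions()]).
#' @return The edited sequence; length is preserved.
#' @examples
#' apply_substitutions("ACGT", substitutions("C", 2, "T"))
#' @export
apply_substitutions <- function(sequence, subs) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  subs <- validate_substitutions(subs)
  if (nrow(subs) == 0L) return(sequence)
  n <- nchar(sequence)
  if (any(subs$pos > n)) {
    stop("substitution position ", max(subs$pos), " beyond sequence end (length ",
         n, ")", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  found <- chars[subs$pos]
  off <- found != subs$ref
  if (any(off)) {
    i <- which(off)[1]
    stop("reference base mismatch at position ", subs$pos[i], ": expected ",
         subs$ref[i], ", found ", found[i], call. = FALSE)
  }
  chars[subs$pos] <- subs$alt
  paste(chars, collapse = "")
}

#' Diff two coordinate-aligned sequences
#'
#' Returns the substitutions turning `ref` into `alt`, in ascending
#' reference coordinates.  Both sequences must have equal length; gapped or
#' indel-containing comparisons belong to the alignment layer, not here.
#'
#' @param ref,alt Equal-length DNA strings.
#' @return A substitution tibble; zero rows when the inputs are identical.
#' @examples
#' diff_sequences("ACGT", "ATGT")
#' @export
diff_sequences <- function(ref, alt) {
  stopifnot(is.character(ref), length(ref) == 1L,
            is.character(alt), length(alt) == 1L)
  if (nchar(ref) != nchar(alt)) {
    stop("diff_sequences() requires equal-length sequences (got ",
         nchar(ref), " and ", nchar(alt), " nt)", call. = FALSE)
  }
  r <- charToRaw(toupper(ref))
  a <- charToRaw(toupper(alt))
  pos <- which(r != a)
  substitutions(
    ref = strsplit(toupper(ref), "")[[1]][pos],
    pos = pos,
    alt = strsplit(toupper(alt), "")[[1]][pos]
  )
}

#' @rdname apply_substitutions
#' @details `invert_substitutions()` swaps reference and alternate bases, so
#'   that applying a substitution set and then its inverse restores the
#'   original sequence.
#' @export
invert_substitutions <- function(subs) {
  subs <- validate_substitutions(subs)
  substitutions(ref = subs$alt, pos = subs$pos, alt = subs$ref)
}
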