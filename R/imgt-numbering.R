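#' IMGT unique-numbering position maps
#'
#' IGHV reference alleles are conventionally numbered on the IMGT unique
#' numbering for V regions: a fixed codon grid (FR1 codons 1-26, CDR1 27-38,
#' FR2 39-55, CDR2 56-65, FR3 66-104) into which each germline is placed,
#' with gaps inserted where a region is shorter than its grid.  Published
#' substitution names (e.g. `G234T`) index this gapped grid, not the raw
#' ungapped sequence, so the package keeps an optional *position map* per
#' allele: an integer vector giving the grid position of every ungapped
#' nucleotide.  Maps come from three sources, in order of preference:
#' IMGT-gapped FASTA input (`.` characters mark the gaps), this constructor
#' (region lengths supplied explicitly), or the identity map.
#'
#' Gap placement follows the IMGT convention: a 25-codon FR1 lacks codon 10;
#' short CDR1/CDR2 loops are gapped in the middle of their grid (the first
#' `ceiling(L/2)` codons sit at the start of the grid, the last
#' `floor(L/2)` at its end); a 38-codon FR3 lacks codon 73.
#'
#' @param seq_length Ungapped nucleotide length of the allele.
#' @param cdr1_len,cdr2_len CDR1-IMGT and CDR2-IMGT lengths in codons
#'   (amino acids), at most 12 and 10.
#' @param fr1_len FR1-IMGT length in codons; 25 for almost all IGHV.
#' @param fr3_gap73 Does the allele lack IMGT position 73 (38-codon FR3)?
#'
#' @return Integer vector of length `seq_length`: `map[i]` is the IMGT
#'   position of ungapped nucleotide `i`.
#'
#' @examples
#' map <- imgt_position_map(296, cdr1_len = 8, cdr2_len = 8)
#' map[210]  # an FR3 nucleotide, shifted by 24 accumulated gap positions
#' @export
imgt_position_map <- function(seq_length, cdr1_len, cdr2_len,
                              fr1_len = 25L, fr3_gap73 = TRUE) {
  stopifnot(fr1_len <= 26L, cdr1_len <= 12L, cdr2_len <= 10L)
  gap_codons <- integer()
  if (fr1_len < 26L) gap_codons <- c(gap_codons, seq(10L, by = -1L, length.out = 26L - fr1_len))
  gap_codons <- c(gap_codons, middle_gaps(27L, 38L, cdr1_len))
  gap_codons <- c(gap_codons, middle_gaps(56L, 65L, cdr2_len))
  if (isTRUE(fr3_gap73)) gap_codons <- c(gap_codons, 73L)
  gap_nt <- sort(c(3L * gap_codons - 2L, 3L * gap_codons - 1L, 3L * gap_codons))
  grid <- setdiff(seq_len(seq_length + length(gap_nt)), gap_nt)
  if (length(grid) < seq_length) {
    # sequence runs past the gapped grid (long alleles); extend linearly
    grid <- c(grid, seq(max(grid) + 1L, length.out = seq_length - length(grid)))
  }
  grid[seq_len(seq_length)]
}

middle_gaps <- function(first, last, len) {
  width <- last - first + 1L
  if (len >= width) return(integer())
  head_n <- ceiling(len / 2)
  tail_n <- floor(len / 2)
  seq.int(first + head_n, last - tail_n)
}

# Map from a gapped sequence string: IMGT reference directories ship alleles
# with "." at gap positions; the map is simply the index of each real base.
position_map_from_gapped <- function(gapped) {
  chars <- strsplit(gapped, "", fixed = TRUE)[[1]]
  which(chars != ".")
}

# Translate ungapped positions to reported (map) coordinates and back.
# A NULL map is the identity.
to_reported_pos <- function(pos, map) {
  if (is.null(map)) return(as.integer(pos))
  stopifnot(all(pos >= 1L), all(pos <= length(map)))
  map[pos]
}

from_reported_pos <- function(pos, map) {
  if (is.null(map)) return(as.integer(pos))
  idx <- match(pos, map)
  if (anyNA(idx)) {
    stop("position(s) ", paste(pos[is.na(idx)], collapse = ", "),
         " do not exist in the allele's coordinate map (IMGT gap position?)",
         call. = FALSE)
  }
  idx
}
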