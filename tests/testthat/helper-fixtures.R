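# shared fixtures: all built in code, no files

# two distant toy alleles with easily countable mismatches
toy_db <- function() {
  set.seed(421)
  a <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = "")
  b_chars <- strsplit(a, "")[[1]]
  flip <- c(10, 40, 70, 100, 130, 145)  # 6 positions apart
  b_chars[flip] <- chartr("ACGT", "CGTA", b_chars[flip])
  germline_db(c("TOYV1-1*01", "TOYV1-2*01"),
              c(a, paste(b_chars, collapse = "")))
}

# plant substitutions into a db allele by ungapped position
plant <- function(db, allele, pos, alt = NULL) {
  s <- db$sequence[match(allele, db$name)]
  ref <- strsplit(s, "")[[1]][pos]
  if (is.null(alt)) alt <- chartr("ACGT", "CGTA", ref)
  apply_substitutions(s, substitutions(ref, pos, alt))
}

# independent brute-force diff used as an oracle against package internals
oracle_diff <- function(ref, alt) {
  rc <- strsplit(ref, "")[[1]]
  ac <- strsplit(alt, "")[[1]]
  out <- data.frame(ref = character(), pos = integer(), alt = character())
  for (i in seq_along(rc)) {
    if (rc[i] != ac[i]) {
      out <- rbind(out, data.frame(ref = rc[i], pos = i, alt = ac[i]))
    }
  }
  out
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

# repertoire of n sequences from one allele: k carriers of substitutions at
# the given ungapped positions, the rest exact copies (no other noise)
planted_repertoire <- function(db, allele, pos, n, k, alt = NULL) {
  base <- db$sequence[match(allele, db$name)]
  novel <- base
  if (length(pos) > 0) {
    ref <- strsplit(base, "")[[1]][pos]
    if (is.null(alt)) alt <- chartr("ACGT", "CGTA", ref)
    novel <- apply_substitutions(base, substitutions(ref, pos, alt))
  }
  tibble::tibble(
    id = sprintf("p%04d", seq_len(n)),
    sequence = c(rep(novel, k), rep(base, n - k)),
    multiplicity = 1L
  )
}
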