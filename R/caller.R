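#' Caller parameters
#'
#' Thresholds for novel-allele prediction from unique IgM sequences.  A
#' substitution is a candidate SNP when it is carried by at least
#' `min_share` of the unique sequences while all *other* substitutions at
#' the same position together stay below `max_discordant`.  The
#' perfect-to-k-mismatch ratio screen (`ratio_trigger`) marks which mismatch
#' classes look genotype-like (ratios under 2:1); it is advisory by default
#' and gating in `strict` mode.
#'
#' @param min_share Identical-mutation prevalence threshold (default 0.20,
#'   the share expected when 1 of up to 4 gene copies is novel is 25%).
#' @param max_discordant Ceiling on other substitutions at the same position
#'   (default 0.02; unique IgM sequences carry few somatic hypermutations, so
#'   genuine SNPs are near-clean).
#' @param ratio_trigger Perfect:k-mismatch ratio below which a class is
#'   inspected (default 2).
#' @param max_snps Largest mismatch class examined / largest substitution
#'   set called (default 4).
#' @param min_unique Minimum unique sequences per allele to attempt a call;
#'   below it the outcome is `"insufficient_depth"`, distinct from a
#'   negative call.
#' @param masked_positions Optional ungapped positions excluded from calling.
#' @param strict Gate candidate evaluation on the ratio screen.
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(min_share = 0.20, max_discordant = 0.02,
                          ratio_trigger = 2, max_snps = 4L,
                          min_unique = 50L, masked_positions = integer(),
                          strict = FALSE) {
  stopifnot(max_discordant > 0, max_discordant < min_share, min_share <= 1,
            ratio_trigger > 0, max_snps >= 1L, min_unique >= 1L)
  structure(list(min_share = min_share, max_discordant = max_discordant,
                 ratio_trigger = ratio_trigger, max_snps = as.integer(max_snps),
                 min_unique = as.integer(min_unique),
                 masked_positions = as.integer(masked_positions),
                 strict = isTRUE(strict)),
            class = "caller_params")
}

profiled_group <- function(group) {
  # indel-containing and unassigned records never enter profiling
  group[group$status == "assigned" & !group$has_indel, , drop = FALSE]
}

#' Perfect-to-mismatch ratio screen
#'
#' Counts unique sequences with exactly 0..`max_snps` mismatches to their
#' assigned allele and forms the ratio of perfect matches to each class.
#' Classes outnumbering the perfect class by more than 1:`ratio_trigger`
#' (ratio below the trigger) are genotype-like: a heterozygous novel allele
#' roughly balances the classes, a homozygous one empties the perfect class.
#'
#' @param group Assignments of one allele (rows of [batch_assign()] output).
#' @param params [caller_params()].
#' @return A tibble with one row per mismatch class `k`: `allele`,
#'   `n_total`, `k`, `n`, `ratio` (`Inf` when the class is empty, 0 when the
#'   perfect class is empty), `triggered`.
#' @export
compute_mismatch_ratios <- function(group, params = caller_params()) {
  group <- profiled_group(group)
  if (nrow(group) == 0L) stop("empty assignment group", call. = FALSE)
  if (length(unique(group$allele)) != 1L) {
    stop("mixed-allele group: ", paste(unique(group$allele), collapse = ", "),
         call. = FALSE)
  }
  ks <- 0:params$max_snps
  counts <- vapply(ks, function(k) sum(group$n_mismatches == k), 0L)
  ratio <- ifelse(counts == 0L, Inf, counts[1] / counts)
  ratio[1] <- NA_real_
  tibble::tibble(
    allele = group$allele[1],
    n_total = nrow(group),
    k = ks,
    n = counts,
    ratio = ratio,
    triggered = !is.na(ratio) & counts > 0L & ratio < params$ratio_trigger
  )
}

#' Per-position substitution profile
#'
#' For every germline position and alternate base, the fraction of unique
#' sequences carrying that substitution.  The denominator at each position
#' is the number of profiled sequences whose aligned interval covers it, so
#' 5'-truncated reads are not penalised.
#'
#' @param group Assignments of one allele.
#' @param db The [germline_db()] the assignments were made against.
#' @return A tibble of class `ig_position_profile` with columns `allele`,
#'   `position` (ungapped), `ref`, `alt`, `count`, `coverage`, `fraction`;
#'   positions with no observed substitution are omitted (fraction 0).
#'   Attributes: `n_seqs` (profiled sequences) and `coverage` (full
#'   per-position coverage vector).
#' @export
build_position_profile <- function(group, db) {
  group <- profiled_group(group)
  if (nrow(group) == 0L) stop("empty assignment group", call. = FALSE)
  allele <- group$allele[1]
  stopifnot(length(unique(group$allele)) == 1L)
  i <- match(allele, db$name)
  if (is.na(i)) stop("allele ", allele, " not in database", call. = FALSE)
  L <- nchar(db$sequence[i])
  starts <- tabulate(group$aligned_start, nbins = L)
  ends <- tabulate(pmin(group$aligned_end, L), nbins = L)
  cov <- cumsum(starts) - c(0L, cumsum(ends)[-L])
  subs <- dplyr::bind_rows(group$mismatches)
  if (nrow(subs) > 0L) {
    tallied <- dplyr::count(subs, .data$ref, .data$pos, .data$alt, name = "count")
  } else {
    tallied <- tibble::tibble(ref = character(), pos = integer(),
                              alt = character(), count = integer())
  }
  out <- tibble::tibble(
    allele = allele,
    position = tallied$pos,
    ref = tallied$ref,
    alt = tallied$alt,
    count = tallied$count,
    coverage = cov[tallied$pos]
  )
  out$fraction <- ifelse(out$coverage > 0L, out$count / out$coverage, 0)
  out <- out[order(out$position, out$alt), ]
  attr(out, "n_seqs") <- nrow(group)
  attr(out, "coverage") <- cov
  class(out) <- c("ig_position_profile", class(tibble::tibble()))
  out
}

#' Candidate SNP calling from a position profile
#'
#' A position/alternate-base pair is a candidate SNP when its fraction
#' reaches `min_share`, the combined fraction of *other* substitutions at
#' that position stays below `max_discordant`, and the position is not
#' masked.  Fewer than `min_unique` profiled sequences yield the
#' `"insufficient_depth"` outcome rather than a (negative) empty candidate
#' list; in `strict` mode an untriggered ratio screen yields
#' `"not_triggered"`.
#'
#' @param profile A [build_position_profile()] result.
#' @param summary Optional [compute_mismatch_ratios()] result (required in
#'   `strict` mode).
#' @param params [caller_params()].
#' @return Candidate substitutions (columns `ref`, `pos`, `alt`, `fraction`,
#'   `discordant`), sorted by position, with attribute `status` one of
#'   `"ok"`, `"insufficient_depth"`, `"not_triggered"`.
#' @export
call_candidate_snps <- function(profile, summary = NULL, params = caller_params()) {
  n_seqs <- attr(profile, "n_seqs")
  empty <- tibble::tibble(ref = character(), pos = integer(), alt = character(),
                          fraction = numeric(), discordant = numeric())
  if (n_seqs < params$min_unique) {
    attr(empty, "status") <- "insufficient_depth"
    return(empty)
  }
  if (params$strict) {
    if (is.null(summary)) {
      stop("strict mode requires the mismatch-ratio summary", call. = FALSE)
    }
    if (!any(summary$triggered)) {
      attr(empty, "status") <- "not_triggered"
      return(empty)
    }
  }
  prof <- tibble::as_tibble(profile)
  if (nrow(prof) > 0L) {
    tot <- stats::aggregate(fraction ~ position, data = prof, FUN = sum)
    prof$discordant <- tot$fraction[match(prof$position, tot$position)] - prof$fraction
  } else {
    prof$discordant <- numeric()
  }
  keep <- prof$fraction >= params$min_share &
    prof$discordant < params$max_discordant &
    !(prof$position %in% params$masked_positions)
  out <- tibble::tibble(ref = prof$ref[keep], pos = prof$position[keep],
                        alt = prof$alt[keep], fraction = prof$fraction[keep],
                        discordant = prof$discordant[keep])
  out <- out[order(out$pos), ]
  attr(out, "status") <- "ok"
  out
}

#' Partition candidate SNPs into co-occurring novel alleles
#'
#' Unique sequences are keyed by their substitution pattern restricted to
#' the candidate positions; every non-empty pattern carried *identically* by
#' at least `min_share` of the sequences, and consisting only of candidate
#' substitutions, is emitted as one novel allele.  Two candidates that never
#' co-occur therefore yield two single-SNP alleles, while candidates riding
#' on the same sequences merge into one multi-SNP allele.  Patterns larger
#' than `max_snps` are reported as out of range, not called.
#'
#' @param group Assignments of one allele.
#' @param candidates Output of [call_candidate_snps()].
#' @param params [caller_params()].
#' @param db The [germline_db()] (for sequence construction and naming).
#' @return A tibble of novel-allele calls: `base_allele`, `novel_name`,
#'   `substitutions` (list column, ungapped), `n_support`, `n_total`,
#'   `share`, `max_discordant`, `novel_sequence`, `note`.  Attribute
#'   `out_of_range` lists any over-sized patterns.
#' @export
check_cooccurrence <- function(group, candidates, params = caller_params(), db) {
  group <- profiled_group(group)
  empty <- empty_calls()
  attr(empty, "out_of_range") <- character()
  if (nrow(candidates) == 0L || nrow(group) == 0L) return(empty)
  allele <- group$allele[1]
  i <- match(allele, db$name)
  cand_tok <- paste0(candidates$ref, candidates$pos, candidates$alt)
  n_total <- nrow(group)

  patterns <- vapply(group$mismatches, function(s) {
    hit <- s$pos %in% candidates$pos
    if (!any(hit)) return("")
    paste(sub_tokens(s[hit, , drop = FALSE], check = FALSE), collapse = "_")
  }, "")
  tab <- table(patterns[patterns != ""])
  out <- empty
  oor <- character()
  for (pat in names(tab)) {
    toks <- strsplit(pat, "_", fixed = TRUE)[[1]]
    if (!all(toks %in% cand_tok)) next  # carries a non-candidate substitution
    share <- as.integer(tab[[pat]]) / n_total
    if (share < params$min_share) next
    if (length(toks) > params$max_snps) {
      oor <- c(oor, pat)
      next
    }
    subs <- parse_sub_tokens(toks)
    novel_seq <- apply_substitutions(db$sequence[i], subs)
    call <- tibble::tibble(
      base_allele = allele,
      novel_name = name_novel_allele(allele, subs, db$position_map[[i]]),
      substitutions = list(subs),
      n_support = as.integer(tab[[pat]]),
      n_total = n_total,
      share = share,
      max_discordant = max(candidates$discordant[match(toks, cand_tok)]),
      novel_sequence = novel_seq,
      note = truncation_note(novel_seq, allele, db)
    )
    out <- dplyr::bind_rows(out, call)
  }
  out <- out[order(out$novel_name), ]
  attr(out, "out_of_range") <- oor
  class(out) <- c("ig_novel_calls", class(tibble::tibble()))
  out
}

empty_calls <- function() {
  out <- tibble::tibble(
    base_allele = character(), novel_name = character(),
    substitutions = list(), n_support = integer(), n_total = integer(),
    share = numeric(), max_discordant = numeric(),
    novel_sequence = character(), note = character()
  )
  class(out) <- c("ig_novel_calls", class(tibble::tibble()))
  out
}

truncation_note <- function(novel_seq, base_allele, db) {
  # a constructed novel sequence that contains an existing shorter allele as
  # an exact substring is the full-length reading of that truncated record;
  # annotate rather than suppress
  shorter <- db$name != base_allele & nchar(db$sequence) < nchar(novel_seq) &
    !db$is_novel
  for (j in which(shorter)) {
    if (grepl(db$sequence[j], novel_seq, fixed = TRUE)) {
      return(paste0("extends truncated allele ", db$name[j]))
    }
  }
  ""
}

#' Predict novel alleles from an assignment table
#'
#' Runs the full caller per allele group: ratio screen, position profile,
#' candidate SNP thresholds, and co-occurrence partitioning.
#'
#' @param assignments [batch_assign()] output.
#' @param db The [germline_db()].
#' @param params [caller_params()].
#' @return An object of class `novel_call_set`: a list with `calls` (the
#'   combined call tibble), `allele_status` (per-allele outcome:
#'   `"called"`, `"negative"`, `"insufficient_depth"`, `"not_triggered"`),
#'   `ratios`, `profiles` (named list) and `params`.  Use [tidy()] /
#'   [glance()] / [ggplot2::autoplot()] on the pieces.
#' @export
call_novel_alleles <- function(assignments, db, params = caller_params()) {
  prof_all <- profiled_group(assignments)
  alleles <- sort(unique(prof_all$allele))
  calls <- empty_calls()
  ratios <- list()
  profiles <- list()
  status <- tibble::tibble(allele = character(), n_total = integer(),
                           status = character(), n_candidates = integer())
  for (a in alleles) {
    group <- prof_all[prof_all$allele == a, ]
    summ <- compute_mismatch_ratios(group, params)
    profile <- build_position_profile(group, db)
    cand <- call_candidate_snps(profile, summ, params)
    st <- attr(cand, "status")
    acalls <- empty_calls()
    if (st == "ok" && nrow(cand) > 0L) {
      acalls <- check_cooccurrence(group, cand, params, db)
    }
    ratios[[a]] <- summ
    profiles[[a]] <- profile
    calls <- dplyr::bind_rows(calls, acalls)
    status <- dplyr::bind_rows(status, tibble::tibble(
      allele = a, n_total = nrow(group),
      status = if (st != "ok") st else if (nrow(acalls) > 0L) "called" else "negative",
      n_candidates = nrow(cand)
    ))
  }
  class(calls) <- c("ig_novel_calls", class(tibble::tibble()))
  structure(list(calls = calls, allele_status = status,
                 ratios = dplyr::bind_rows(ratios), profiles = profiles,
                 params = params),
            class = "novel_call_set")
}

#' @export
print.novel_call_set <- function(x, ...) {
  cat("<novel_call_set> ", nrow(x$allele_status), " alleles examined, ",
      nrow(x$calls), " novel allele call(s)\n", sep = "")
  if (nrow(x$calls) > 0L) {
    print(x$calls[, c("novel_name", "n_support", "n_total", "share")])
  }
  invisible(x)
}

#' Tidy and summarise novel-allele call sets
#'
#' @param x A `novel_call_set`.
#' @param ... Unused.
#' @return `tidy()` returns the call tibble with token-formatted
#'   substitutions; `glance()` a one-row summary.
#' @method tidy novel_call_set
#' @export
tidy.novel_call_set <- function(x, ...) {
  calls <- tibble::as_tibble(x$calls)
  calls$substitutions <- vapply(calls$substitutions, function(s) {
    paste(sub_tokens(s, check = FALSE), collapse = "_")
  }, "")
  calls
}

#' @rdname tidy.novel_call_set
#' @method glance novel_call_set
#' @export
glance.novel_call_set <- function(x, ...) {
  tibble::tibble(
    n_alleles_examined = nrow(x$allele_status),
    n_called = sum(x$allele_status$status == "called"),
    n_negative = sum(x$allele_status$status == "negative"),
    n_insufficient_depth = sum(x$allele_status$status == "insufficient_depth"),
    n_calls = nrow(x$calls),
    max_share = if (nrow(x$calls) > 0L) max(x$calls$share) else NA_real_
  )
}

#' Plot a per-position substitution profile
#'
#' The classic novel-allele diagnostic: percent of unique IgM sequences
#' mutated at each germline position, coloured by alternate base, with the
#' calling threshold as a dashed line.  A genuine novel-allele SNP towers
#' above the low somatic-hypermutation noise floor.
#'
#' @param object An `ig_position_profile`.
#' @param min_share Threshold line to draw (default 0.20).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ig_position_profile
#' @export
autoplot.ig_position_profile <- function(object, min_share = 0.20, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = 100 * .data$fraction,
                                   fill = .data$alt)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = 100 * min_share, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(A = "#3366CC", C = "#CC6699",
                                          G = "#222222", T = "#CC2222"),
                               name = "substitution") +
    ggplot2::labs(x = "germline position (ungapped)",
                  y = "% unique IgM sequences mutated",
                  title = object$allele[1]) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ig_position_profile
#' @export
plot_profile <- function(object, min_share = 0.20, ...) {
  autoplot.ig_position_profile(object, min_share = min_share, ...)
}
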