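# Arm-level quantification and the arm-selection statistic
# omega = 5p / (5p + 3p), with count-gated dominance classification and
# replicate-unanimous arm-switch calls between conditions.

#' Switch-calling parameters
#'
#' @param min_count dominance requires `max(count5p, count3p) > min_count`
#'   per sample (strict; default 50).
#' @param low_cut omega below this indicates 3p dominance (default 0.3,
#'   strict inequality).
#' @param high_cut omega above this indicates 5p dominance (default 0.7,
#'   strict inequality).
#' @param require_all_replicates when TRUE (default) every replicate of both
#'   conditions must carry an opposite dominant label for a switch call;
#'   when FALSE, replicates classified `insufficient` or `unclassified` are
#'   dropped and unanimity is required among the remainder (at least one
#'   replicate per condition).
#' @return list of class `switch_params`.
#' @export
switch_params <- function(min_count = 50L, low_cut = 0.3, high_cut = 0.7,
                          require_all_replicates = TRUE) {
  stopifnot(low_cut >= 0, low_cut < high_cut, high_cut <= 1, min_count >= 0)
  structure(list(min_count = min_count, low_cut = low_cut, high_cut = high_cut,
                 require_all_replicates = isTRUE(require_all_replicates)),
            class = "switch_params")
}

#' Quantify reads onto hairpin arms
#'
#' Each read is aligned ungapped, sense strand only, against every hairpin;
#' the best alignment is the one with the fewest mismatches (leftmost on
#' ties within a hairpin). A read whose best alignment has at most
#' `max_mismatch` mismatches increments `count5p` (resp. `count3p`) of every
#' best-tied hairpin when the aligned interval covers at least 50% of the
#' read length on that arm; reads overlapping both arms equally, or neither
#' arm sufficiently, increment `unassigned`. Multi-mapping reads count once
#' per tied hairpin (no fractional counts).
#'
#' @param reads character vector of read sequences, or a read table with a
#'   `seq` column. Reads are assumed QC-filtered.
#' @param loci hairpin loci data.frame (see [read_hairpin_annotation()]).
#' @param max_mismatch maximum mismatches for a valid alignment (default 0).
#' @return data.frame with one row per hairpin: `hairpin_id`, `count5p`,
#'   `count3p`, `unassigned`, plus an `unmapped` attribute counting reads
#'   matching no hairpin.
#' @export
quantify_arms <- function(reads, loci, max_mismatch = 0L) {
  if (is.data.frame(reads)) reads <- reads$seq
  if (nrow(loci) == 0L) stop("empty hairpin list")
  reads <- normalize_rna(reads)
  out <- data.frame(hairpin_id = loci$hairpin_id,
                    count5p = 0L, count3p = 0L, unassigned = 0L,
                    stringsAsFactors = FALSE)
  if (!length(reads)) {
    attr(out, "unmapped") <- 0L
    return(out)
  }
  tab <- table(reads)
  uniq <- names(tab)
  mult <- as.integer(tab)
  subjects <- lapply(loci$sequence, function(s)
    Biostrings::RNAString(s))
  hlen <- nchar(loci$sequence)
  unmapped <- 0L
  nh <- nrow(loci)
  for (k in seq_along(uniq)) {
    u <- uniq[k]
    w <- nchar(u)
    pat <- Biostrings::RNAString(u)
    best_mm <- rep(NA_integer_, nh)
    best_at <- rep(NA_integer_, nh)
    for (h in seq_len(nh)) {
      nstart <- hlen[h] - w + 1L
      if (nstart < 1L) next
      ned <- Biostrings::neditStartingAt(pat, subjects[[h]],
                                         starting.at = seq_len(nstart),
                                         with.indels = FALSE)
      m <- min(ned)
      if (m <= max_mismatch) {
        best_mm[h] <- m
        best_at[h] <- which.min(ned)  # leftmost best
      }
    }
    if (all(is.na(best_mm))) {
      unmapped <- unmapped + mult[k]
      next
    }
    gbest <- min(best_mm, na.rm = TRUE)
    for (h in which(!is.na(best_mm) & best_mm == gbest)) {
      s0 <- best_at[h] - 1L  # 0-based alignment start
      arm <- assign_arm(s0, w,
                        loci$arm5p_start[h], loci$arm5p_end[h],
                        loci$arm3p_start[h], loci$arm3p_end[h])
      col <- switch(arm, `5p` = "count5p", `3p` = "count3p", "unassigned")
      out[[col]][h] <- out[[col]][h] + mult[k]
    }
  }
  attr(out, "unmapped") <- unmapped
  out
}

# 50% read-length overlap rule; both arms -> larger overlap, tie -> none.
assign_arm <- function(start0, width, a5s, a5e, a3s, a3e) {
  end0 <- start0 + width
  ov5 <- max(0L, min(end0, a5e) - max(start0, a5s))
  ov3 <- max(0L, min(end0, a3e) - max(start0, a3s))
  thr <- width / 2
  hit5 <- ov5 >= thr
  hit3 <- ov3 >= thr
  if (hit5 && hit3) {
    if (ov5 > ov3) "5p" else if (ov3 > ov5) "3p" else "none"
  } else if (hit5) "5p" else if (hit3) "3p" else "none"
}

#' Arm-selection statistic omega
#'
#' `omega = count5p / (count5p + count3p)`, in `[0, 1]`; values near 1
#' indicate 5p preference, near 0 indicate 3p preference. Undefined (`NA`)
#' when both counts are zero.
#'
#' @param count5p,count3p non-negative read counts (vectorized).
#' @return numeric vector of omega values.
#' @export
compute_omega <- function(count5p, count3p) {
  if (any(count5p < 0) || any(count3p < 0)) stop("negative counts")
  tot <- count5p + count3p
  ifelse(tot == 0, NA_real_, count5p / tot)
}

#' Classify per-sample arm dominance
#'
#' `insufficient` when `max(count5p, count3p) <= min_count` (the >50 absolute
#' count gate, strict); otherwise `dominant3p` iff `omega < low_cut`,
#' `dominant5p` iff `omega > high_cut`, else `unclassified`. Boundary values
#' (`omega == low_cut` or `== high_cut`) are unclassified.
#'
#' @param omega omega values from [compute_omega()] on the same counts.
#' @param count5p,count3p the underlying counts (vectorized).
#' @param params [switch_params()].
#' @return character vector over \{dominant5p, dominant3p, unclassified,
#'   insufficient\}.
#' @export
classify_dominance <- function(omega, count5p, count3p, params = switch_params()) {
  n <- max(length(omega), length(count5p), length(count3p))
  omega <- rep_len(omega, n)
  count5p <- rep_len(count5p, n)
  count3p <- rep_len(count3p, n)
  out <- rep("unclassified", n)
  ins <- pmax(count5p, count3p) <= params$min_count
  out[ins] <- "insufficient"
  ok <- !ins & !is.na(omega)
  out[ok & omega < params$low_cut] <- "dominant3p"
  out[ok & omega > params$high_cut] <- "dominant5p"
  out
}

#' Build per-sample omega profiles from an arm count table
#'
#' @param arm_counts data.frame with `hairpin_id`, `sample_id`, `count5p`,
#'   `count3p` rows.
#' @param params [switch_params()].
#' @return the table with `omega` and `dominance` columns appended.
#' @export
omega_profiles <- function(arm_counts, params = switch_params()) {
  arm_counts$omega <- compute_omega(arm_counts$count5p, arm_counts$count3p)
  arm_counts$dominance <- classify_dominance(arm_counts$omega,
                                             arm_counts$count5p,
                                             arm_counts$count3p, params)
  arm_counts
}

condition_label <- function(accession, tissue, time_h) {
  paste(accession, tissue, paste0(time_h, "h"), sep = ":")
}

# Evaluate one ordered condition pair for one hairpin. `dom_a`/`dom_b` are
# per-replicate dominance labels. Returns the pair of opposite dominant
# labels, or NULL when no switch.
evaluate_switch <- function(dom_a, dom_b, require_all_replicates = TRUE) {
  if (!length(dom_a) || !length(dom_b)) return(NULL)
  dominant <- c("dominant5p", "dominant3p")
  if (require_all_replicates) {
    if (any(!(dom_a %in% dominant)) || any(!(dom_b %in% dominant))) return(NULL)
  } else {
    dom_a <- dom_a[dom_a %in% dominant]
    dom_b <- dom_b[dom_b %in% dominant]
    if (!length(dom_a) || !length(dom_b)) return(NULL)
  }
  ua <- unique(dom_a)
  ub <- unique(dom_b)
  if (length(ua) != 1L || length(ub) != 1L || ua == ub) return(NULL)
  c(ua, ub)
}

#' Call replicate-consistent arm switches between conditions
#'
#' A condition is an (accession, tissue, time_h) cell of the design. For
#' every hairpin and condition pair, a switch is called iff every replicate
#' of one condition shows the same dominant arm and every replicate of the
#' other shows the opposite dominant arm (see [switch_params()] for the
#' relaxed mode).
#'
#' @param profiles omega profile table from [omega_profiles()].
#' @param samples sample sheet (see [read_sample_sheet()]).
#' @param params [switch_params()].
#' @param compare which condition pairs to test: `"default"` = all pairs
#'   within an accession (differing in tissue or time) plus same
#'   tissue/time pairs across accessions; `"within_accession"`,
#'   `"across_accession"`, or `"all"`.
#' @return data.frame of switch calls: `hairpin_id`, `condition_a`,
#'   `condition_b`, `dominance_a`, `dominance_b`, `omega_a`, `omega_b`
#'   (per-replicate omega values, semicolon-joined).
#' @export
call_arm_switches <- function(profiles, samples, params = switch_params(),
                              compare = c("default", "within_accession",
                                          "across_accession", "all")) {
  compare <- match.arg(compare)
  conds <- unique(samples[, c("accession", "tissue", "time_h")])
  conds <- conds[order(conds$accession, conds$tissue, conds$time_h), , drop = FALSE]
  conds$label <- condition_label(conds$accession, conds$tissue, conds$time_h)
  if (nrow(conds) < 2L) stop("need at least two conditions")
  samples$cond <- condition_label(samples$accession, samples$tissue, samples$time_h)

  pair_ok <- function(i, j) {
    same_acc <- conds$accession[i] == conds$accession[j]
    same_cell <- conds$tissue[i] == conds$tissue[j] &&
      conds$time_h[i] == conds$time_h[j]
    switch(compare,
           default = same_acc || same_cell,
           within_accession = same_acc,
           across_accession = !same_acc && same_cell,
           all = TRUE)
  }

  prof_by_cond <- split(profiles,
                        samples$cond[match(profiles$sample_id, samples$sample_id)])
  empty <- setdiff(conds$label, names(prof_by_cond))
  if (length(empty)) {
    warning("condition(s) with zero replicates skipped: ",
            paste(empty, collapse = ", "))
    conds <- conds[!(conds$label %in% empty), , drop = FALSE]
  }

  calls <- list()
  hairpins <- unique(profiles$hairpin_id)
  # index: per condition, per hairpin rows ordered by sample_id for stable output
  cond_tabs <- lapply(prof_by_cond, function(df) df[order(df$sample_id), , drop = FALSE])
  for (i in seq_len(nrow(conds) - 1L)) {
    for (j in seq((i + 1L), nrow(conds))) {
      if (!pair_ok(i, j)) next
      la <- conds$label[i]; lb <- conds$label[j]
      ta <- cond_tabs[[la]]; tb <- cond_tabs[[lb]]
      for (hp in hairpins) {
        ra <- ta[ta$hairpin_id == hp, , drop = FALSE]
        rb <- tb[tb$hairpin_id == hp, , drop = FALSE]
        sw <- evaluate_switch(ra$dominance, rb$dominance,
                              params$require_all_replicates)
        if (is.null(sw)) next
        calls[[length(calls) + 1L]] <- data.frame(
          hairpin_id = hp, condition_a = la, condition_b = lb,
          dominance_a = sw[1], dominance_b = sw[2],
          omega_a = paste(format(ra$omega, digits = 6, trim = TRUE), collapse = ";"),
          omega_b = paste(format(rb$omega, digits = 6, trim = TRUE), collapse = ";"),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(calls)) {
    return(data.frame(hairpin_id = character(), condition_a = character(),
                      condition_b = character(), dominance_a = character(),
                      dominance_b = character(), omega_a = character(),
                      omega_b = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(calls, make.row.names = FALSE))
}
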