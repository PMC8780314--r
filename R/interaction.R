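# miRNA:lncRNA interaction screening: (1) a penalty-based
# seed-complementarity duplex scanner (plant-style scoring: mismatch 1,
# G:U wobble 0.5, gap 2, seed positions weighted x2) and (2) pairing of
# antagonistic differential-expression calls in the same contrast.

#' Duplex scanner parameters
#'
#' Plant-style complementarity scoring. The seed is miRNA positions
#' `seed_start..seed_end`, 1-based from the 5' end; penalties within the
#' seed are multiplied by `seed_weight`, and at most `max_seed_mismatch`
#' non-Watson-Crick pairs (wobbles included) are tolerated there. One gap
#' (miRNA or target bulge) is allowed outside the seed.
#'
#' @param seed_start,seed_end seed interval on the miRNA (defaults 2 and 8).
#' @param max_seed_mismatch maximum non-WC pairs in the seed (default 0).
#' @param wobble_penalty G:U pair penalty (default 0.5).
#' @param mismatch_penalty non-pairing penalty (default 1).
#' @param gap_penalty single-base bulge penalty (default 2).
#' @param max_total_penalty report sites with total penalty at most this
#'   (default 4).
#' @param seed_weight multiplier on penalties inside the seed (default 2).
#' @return list of class `duplex_params`.
#' @export
duplex_params <- function(seed_start = 2L, seed_end = 8L, max_seed_mismatch = 0L,
                          wobble_penalty = 0.5, mismatch_penalty = 1.0,
                          gap_penalty = 2.0, max_total_penalty = 4.0,
                          seed_weight = 2.0) {
  stopifnot(seed_start >= 1L, seed_start < seed_end)
  structure(list(seed_start = as.integer(seed_start),
                 seed_end = as.integer(seed_end),
                 max_seed_mismatch = as.integer(max_seed_mismatch),
                 wobble_penalty = wobble_penalty,
                 mismatch_penalty = mismatch_penalty,
                 gap_penalty = gap_penalty,
                 max_total_penalty = max_total_penalty,
                 seed_weight = seed_weight),
            class = "duplex_params")
}

# Per-column penalty for pattern char p (complement of the miRNA base) vs
# target char t: equality is Watson-Crick; miRNA G : target U shows as
# p == "C", t == "U", miRNA U : target G as p == "A", t == "G".
pair_penalties <- function(p, t, params) {
  wc <- p == t
  wobble <- (p == "C" & t == "U") | (p == "A" & t == "G")
  pen <- ifelse(wc, 0, ifelse(wobble, params$wobble_penalty,
                              params$mismatch_penalty))
  list(pen = pen, wc = wc)
}

# Alignment templates for a miRNA of length L: the ungapped one plus single
# miRNA-bulge and target-bulge variants with the gap outside the seed.
# Each template: mirna_pos[j] (NA = target bulge column), offset[j] (column
# j pairs window position offset[j]), width, gaps.
duplex_templates <- function(L, params) {
  seed <- seq(params$seed_start, min(params$seed_end, L))
  tpl <- list(list(mirna_pos = L:1, offset = seq_len(L), width = L, gaps = 0L))
  for (g in setdiff(2:(L - 1L), seed)) {          # miRNA base g unpaired
    v <- setdiff(L:1, g)
    tpl[[length(tpl) + 1L]] <- list(mirna_pos = v, offset = seq_len(L - 1L),
                                    width = L - 1L, gaps = 1L, mirna_bulge = g)
  }
  for (o in 2:L) {                                 # target base bulged at column o
    flank <- c(L + 2L - o, L + 1L - o)             # miRNA positions around bulge
    if (any(flank %in% seed)) next
    tpl[[length(tpl) + 1L]] <- list(
      mirna_pos = L:1,
      offset = c(seq_len(o - 1L), seq(o + 1L, L + 1L)),
      width = L + 1L, gaps = 1L, target_bulge = o)
  }
  tpl
}

#' Find complementarity sites for a miRNA on a target sequence
#'
#' Scans every target window (ungapped plus single-bulge variants outside
#' the seed), scoring Watson-Crick pairs 0, G:U wobbles `wobble_penalty`,
#' other pairs `mismatch_penalty` and bulges `gap_penalty`, with seed
#' penalties multiplied by `seed_weight`. A site is reported when its seed
#' mismatch count is at most `max_seed_mismatch` and its total penalty at
#' most `max_total_penalty`; overlapping sites are reduced to the
#' minimum-penalty one (ties to the leftmost on the target).
#'
#' @param mirna miRNA sequence (16-30 nt, 5'->3').
#' @param target target sequence, at least as long as the miRNA.
#' @param params [duplex_params()].
#' @param mirna_id,target_id identifiers for the output.
#' @return data.frame: `mirna_id`, `target_id`, `start`, `end` (0-based
#'   half-open on the target), `penalty`, `seed_mismatch`, `aln_mirna`
#'   (3'->5'), `aln_bars`, `aln_target` (5'->3').
#' @export
find_duplex_sites <- function(mirna, target, params = duplex_params(),
                              mirna_id = "mirna", target_id = "target") {
  mirna <- normalize_rna(mirna)
  target <- normalize_rna(target)
  L <- nchar(mirna)
  if (L < 16L || L > 30L) stop("miRNA length must be in [16, 30]")
  if (nchar(target) < L) stop("target shorter than miRNA")
  if (params$seed_end > L) stop("seed_end exceeds miRNA length")
  mchars <- strsplit(mirna, "", fixed = TRUE)[[1]]
  cchars <- strsplit(comp_rna(mirna), "", fixed = TRUE)[[1]]
  tchars <- strsplit(target, "", fixed = TRUE)[[1]]
  Tn <- length(tchars)
  seed <- seq(params$seed_start, params$seed_end)

  hits <- list()
  for (tpl in duplex_templates(L, params)) {
    nstart <- Tn - tpl$width + 1L
    if (nstart < 1L) next
    starts <- seq_len(nstart)
    total <- rep(tpl$gaps * params$gap_penalty, nstart)
    seedmm <- integer(nstart)
    for (j in seq_along(tpl$offset)) {
      i <- tpl$mirna_pos[j]
      tc <- tchars[starts + tpl$offset[j] - 1L]
      pp <- pair_penalties(rep(cchars[i], nstart), tc, params)
      w <- if (i %in% seed) params$seed_weight else 1
      total <- total + pp$pen * w
      if (i %in% seed) seedmm <- seedmm + !pp$wc
    }
    ok <- which(seedmm <= params$max_seed_mismatch &
                  total <= params$max_total_penalty + 1e-9)
    for (t in ok) {
      hits[[length(hits) + 1L]] <- list(start0 = t - 1L,
                                        end0 = t - 1L + tpl$width,
                                        penalty = total[t],
                                        seed_mismatch = seedmm[t],
                                        tpl = tpl)
    }
  }
  if (!length(hits)) return(empty_duplex_sites())

  # overlap reduction: greedy minimum penalty, ties -> leftmost
  pen <- vapply(hits, `[[`, numeric(1), "penalty")
  st <- vapply(hits, `[[`, integer(1), "start0")
  ord <- order(pen, st)
  chosen <- list()
  taken <- logical(length(hits))
  for (k in ord) {
    if (taken[k]) next
    chosen[[length(chosen) + 1L]] <- hits[[k]]
    ov <- st < hits[[k]]$end0 &
      vapply(hits, `[[`, integer(1), "end0") > hits[[k]]$start0
    taken[ov] <- TRUE
  }
  chosen <- chosen[order(vapply(chosen, `[[`, integer(1), "start0"))]

  do.call(rbind, lapply(chosen, function(h) {
    aln <- render_duplex(mchars, cchars, tchars, h, params)
    data.frame(mirna_id = mirna_id, target_id = target_id,
               start = h$start0, end = h$end0,
               penalty = h$penalty, seed_mismatch = h$seed_mismatch,
               aln_mirna = aln[1], aln_bars = aln[2], aln_target = aln[3],
               stringsAsFactors = FALSE)
  }))
}

empty_duplex_sites <- function() {
  data.frame(mirna_id = character(), target_id = character(),
             start = integer(), end = integer(), penalty = numeric(),
             seed_mismatch = integer(), aln_mirna = character(),
             aln_bars = character(), aln_target = character(),
             stringsAsFactors = FALSE)
}

# Paired alignment strings: miRNA 3'->5' over bars over target 5'->3'.
render_duplex <- function(mchars, cchars, tchars, hit, params) {
  tpl <- hit$tpl
  win <- tchars[(hit$start0 + 1L):(hit$end0)]
  ncol_ <- tpl$width
  mline <- character(ncol_); bline <- character(ncol_); tline <- win
  col2row <- integer(0)
  if (!is.null(tpl$target_bulge)) {
    # column tpl$target_bulge of the window is unpaired target
    jj <- 1L
    for (cidx in seq_len(ncol_)) {
      if (cidx == tpl$target_bulge) { mline[cidx] <- "-"; bline[cidx] <- " "; next }
      i <- tpl$mirna_pos[jj]
      mline[cidx] <- mchars[i]
      bline[cidx] <- bar_char(cchars[i], win[cidx], params)
      jj <- jj + 1L
    }
  } else if (!is.null(tpl$mirna_bulge)) {
    # insert the bulged miRNA base as a column with a target gap
    g <- tpl$mirna_bulge
    out_m <- character(0); out_b <- character(0); out_t <- character(0)
    inserted <- FALSE
    for (j in seq_len(ncol_)) {
      i <- tpl$mirna_pos[j]
      if (!inserted && i < g) {   # positions descend; bulge sits before first i < g
        out_m <- c(out_m, mchars[g]); out_b <- c(out_b, " "); out_t <- c(out_t, "-")
        inserted <- TRUE
      }
      out_m <- c(out_m, mchars[i])
      out_b <- c(out_b, bar_char(cchars[i], win[j], params))
      out_t <- c(out_t, win[j])
    }
    if (!inserted) { out_m <- c(out_m, mchars[g]); out_b <- c(out_b, " "); out_t <- c(out_t, "-") }
    mline <- out_m; bline <- out_b; tline <- out_t
  } else {
    for (j in seq_len(ncol_)) {
      i <- tpl$mirna_pos[j]
      mline[j] <- mchars[i]
      bline[j] <- bar_char(cchars[i], win[j], params)
    }
  }
  c(paste(mline, collapse = ""), paste(bline, collapse = ""),
    paste(tline, collapse = ""))
}

bar_char <- function(p, t, params) {
  if (p == t) "|" else if ((p == "C" && t == "U") || (p == "A" && t == "G")) "o" else " "
}

#' Scan many miRNA/target pairs for duplex sites
#'
#' @param mirnas,targets named character vectors of sequences.
#' @param params [duplex_params()].
#' @return row-bound site table over all pairs (possibly empty).
#' @export
scan_duplex_pairs <- function(mirnas, targets, params = duplex_params()) {
  out <- list(empty_duplex_sites())
  for (mi in names(mirnas)) {
    for (ti in names(targets)) {
      out[[length(out) + 1L]] <-
        find_duplex_sites(mirnas[[mi]], targets[[ti]], params,
                          mirna_id = mi, target_id = ti)
    }
  }
  do.call(rbind, out)
}

#' Screen miRNA:lncRNA pairs for antagonistic expression with a duplex site
#'
#' The two screening criteria: (1) the pair has at least one complementarity
#' site; (2) in the same contrast, the miRNA and the lncRNA pass their
#' respective differential-expression screens with opposite directions.
#'
#' @param mirna_de,lncrna_de `contrast_result` tables (row-bound over
#'   contrasts is fine); both must carry exactly the same set of contrast
#'   labels (`group_a` vs `group_b`), otherwise a hard error.
#' @param sites duplex site table (see [scan_duplex_pairs()]); `target_id`
#'   is matched against lncRNA feature ids.
#' @return data.frame of interaction calls: `mirna_id`, `lncrna_id`,
#'   `contrast`, `mirna_direction`, `lncrna_direction`, `site_start`,
#'   `site_end`, `penalty`, `alignment`. Directions are always opposite.
#' @export
screen_interactions <- function(mirna_de, lncrna_de, sites) {
  mirna_de$contrast <- paste(mirna_de$group_a, "vs", mirna_de$group_b)
  lncrna_de$contrast <- paste(lncrna_de$group_a, "vs", lncrna_de$group_b)
  cm <- sort(unique(mirna_de$contrast))
  cl <- sort(unique(lncrna_de$contrast))
  if (!identical(cm, cl))
    stop("contrast label mismatch between miRNA and lncRNA DE sets")
  calls <- list()
  for (ct in cm) {
    md <- mirna_de[mirna_de$contrast == ct, , drop = FALSE]
    ld <- lncrna_de[lncrna_de$contrast == ct, , drop = FALSE]
    for (k in seq_len(nrow(sites))) {
      s <- sites[k, ]
      dm <- md$direction[md$feature_id == s$mirna_id]
      dl <- ld$direction[ld$feature_id == s$target_id]
      if (!length(dm) || !length(dl)) next
      dm <- dm[1]; dl <- dl[1]
      if (!(dm %in% c("up", "down")) || !(dl %in% c("up", "down"))) next
      if (dm == dl) next
      calls[[length(calls) + 1L]] <- data.frame(
        mirna_id = s$mirna_id, lncrna_id = s$target_id, contrast = ct,
        mirna_direction = dm, lncrna_direction = dl,
        site_start = s$start, site_end = s$end, penalty = s$penalty,
        alignment = paste(s$aln_mirna, s$aln_bars, s$aln_target, sep = "&"),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(calls)) {
    return(data.frame(mirna_id = character(), lncrna_id = character(),
                      contrast = character(), mirna_direction = character(),
                      lncrna_direction = character(), site_start = integer(),
                      site_end = integer(), penalty = numeric(),
                      alignment = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, c(calls, make.row.names = FALSE))
  stopifnot(all(out$mirna_direction != out$lncrna_direction))  # type invariant
  out
}

#' Predict miRNA target sites over labelled transcript regions
#'
#' Runs [find_duplex_sites()] per region (5UTR / CDS / 3UTR / other) and
#' attaches the region label. Sites spanning a region boundary are not
#' found: scanning is strictly per-region.
#'
#' @param mirna miRNA sequence.
#' @param regions data.frame with `region_id`, `region_type` (one of 5UTR,
#'   CDS, 3UTR, other) and `sequence` columns.
#' @param params [duplex_params()].
#' @param mirna_id identifier for the output.
#' @return site table with `region_id` and `region_type` columns appended.
#' @export
predict_targets <- function(mirna, regions, params = duplex_params(),
                            mirna_id = "mirna") {
  if (!nrow(regions)) {
    out <- empty_duplex_sites()
    out$region_id <- character(0)
    out$region_type <- character(0)
    return(out)
  }
  if (anyDuplicated(regions$region_id))
    stop("duplicate region_id: ",
         regions$region_id[which(duplicated(regions$region_id))[1]])
  bad <- setdiff(unique(regions$region_type), c("5UTR", "CDS", "3UTR", "other"))
  if (length(bad)) stop("unknown region_type: ", paste(bad, collapse = ", "))
  out <- lapply(seq_len(nrow(regions)), function(i) {
    s <- find_duplex_sites(mirna, regions$sequence[i], params,
                           mirna_id = mirna_id,
                           target_id = regions$region_id[i])
    if (nrow(s)) {
      s$region_id <- regions$region_id[i]
      s$region_type <- regions$region_type[i]
    } else {
      s$region_id <- character(0)
      s$region_type <- character(0)
    }
    s
  })
  do.call(rbind, out)
}
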