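# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use different code paths (character loops, choose()-based enumeration)
# from the implementation they check.

ALPHA_RNA <- c("A", "C", "G", "U")

rand_rna <- function(len) paste(sample(ALPHA_RNA, len, replace = TRUE), collapse = "")

# A hand-built two-hairpin locus table: arms 21 nt, loops 14 nt.
tiny_loci <- function(seed = 42) {
  set.seed(seed)
  arm5 <- c(rand_rna(21), rand_rna(21))
  loop <- c(rand_rna(14), rand_rna(14))
  arm3 <- c(rand_rna(21), rand_rna(21))
  seqs <- paste0(arm5, loop, arm3)
  data.frame(
    hairpin_id = c("hpA", "hpB"), sequence = seqs,
    arm5p_start = 0L, arm5p_end = 21L,
    arm3p_start = 35L, arm3p_end = 56L,
    mature5p_id = c("hpA-5p", "hpB-5p"), mature3p_id = c("hpA-3p", "hpB-3p"),
    stringsAsFactors = FALSE
  )
}

make_reads <- function(seqs, phred = 35L) {
  data.frame(id = sprintf("r%04d", seq_along(seqs)), seq = seqs,
             qual = strrep(rawToChar(as.raw(33L + phred)), nchar(seqs)),
             stringsAsFactors = FALSE)
}

# Exact two-sided minlike binomial p-value by full enumeration with
# choose()-based probabilities (independent of dbinom-in-log-space).
oracle_binom_p <- function(A, N, pi) {
  if (N == 0) return(1.0)
  probs <- vapply(0:N, function(k) choose(N, k) * pi^k * (1 - pi)^(N - k),
                  numeric(1))
  pobs <- probs[A + 1L]
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# Brute-force ungapped duplex scorer: loops characters, no templates.
# Returns data.frame(start0, penalty, seed_mm) for every window.
oracle_scan_ungapped <- function(mirna, target, params = duplex_params()) {
  m <- strsplit(mirna, "", fixed = TRUE)[[1]]
  t <- strsplit(target, "", fixed = TRUE)[[1]]
  L <- length(m)
  seed <- params$seed_start:params$seed_end
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  res <- lapply(seq_len(length(t) - L + 1L), function(st) {
    pen <- 0; smm <- 0L
    for (i in seq_len(L)) {
      tb <- t[st + (L - i)]          # miRNA pos i pairs antiparallel
      p <- if (tb == wc[[m[i]]]) 0
      else if ((m[i] == "G" && tb == "U") || (m[i] == "U" && tb == "G"))
        params$wobble_penalty
      else params$mismatch_penalty
      if (i %in% seed) {
        pen <- pen + p * params$seed_weight
        if (p > 0) smm <- smm + 1L
      } else pen <- pen + p
    }
    data.frame(start0 = st - 1L, penalty = pen, seed_mm = smm)
  })
  do.call(rbind, res)
}

# Rescore a reported alignment triple independently (self-consistency).
oracle_rescore_alignment <- function(aln_mirna, aln_bars, aln_target,
                                     params = duplex_params(), mirna_len) {
  m <- strsplit(aln_mirna, "", fixed = TRUE)[[1]]
  t <- strsplit(aln_target, "", fixed = TRUE)[[1]]
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  seed <- params$seed_start:params$seed_end
  pen <- 0
  # mirna line is 3'->5': miRNA position of column j counts non-gap chars
  # from the right
  pos <- rev(cumsum(rev(m != "-")))
  for (j in seq_along(m)) {
    if (m[j] == "-" || t[j] == "-") { pen <- pen + params$gap_penalty; next }
    p <- if (t[j] == wc[[m[j]]]) 0
    else if ((m[j] == "G" && t[j] == "U") || (m[j] == "U" && t[j] == "G"))
      params$wobble_penalty
    else params$mismatch_penalty
    if (pos[j] %in% seed) p <- p * params$seed_weight
    pen <- pen + p
  }
  pen
}

# Independent switch-caller: per hairpin/condition-pair unanimity check by
# plain loops over the generator's true counts.
oracle_switch_calls <- function(arm_counts, design, params = switch_params()) {
  design$cond <- paste(design$accession, design$tissue,
                       paste0(design$time_h, "h"), sep = ":")
  arm_counts$cond <- design$cond[match(arm_counts$sample_id, design$sample_id)]
  conds <- sort(unique(design$cond))
  out <- list()
  for (hp in unique(arm_counts$hairpin_id)) {
    sub <- arm_counts[arm_counts$hairpin_id == hp, ]
    dom <- lapply(conds, function(cn) {
      rows <- sub[sub$cond == cn, ]
      vapply(seq_len(nrow(rows)), function(i) {
        c5 <- rows$count5p[i]; c3 <- rows$count3p[i]
        if (max(c5, c3) <= params$min_count) return("insufficient")
        w <- c5 / (c5 + c3)
        if (w < params$low_cut) "dominant3p"
        else if (w > params$high_cut) "dominant5p"
        else "unclassified"
      }, character(1))
    })
    names(dom) <- conds
    for (i in seq_len(length(conds) - 1L)) for (j in (i + 1L):length(conds)) {
      da <- dom[[i]]; db <- dom[[j]]
      if (all(da == "dominant5p") && all(db == "dominant3p") ||
          all(da == "dominant3p") && all(db == "dominant5p")) {
        out[[length(out) + 1L]] <- data.frame(
          hairpin_id = hp, condition_a = conds[i], condition_b = conds[j],
          dominance_a = da[1], dominance_b = db[1], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(data.frame(hairpin_id = character(),
                                      condition_a = character(),
                                      condition_b = character(),
                                      dominance_a = character(),
                                      dominance_b = character()))
  do.call(rbind, c(out, make.row.names = FALSE))
}
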