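# Seeded synthetic small RNA-seq generator: hairpins with annotated arms,
# arm-derived FASTQ reads with negative-binomial depth and planted dominance
# shifts, lncRNAs with planted miRNA-complementary sites, expression
# matrices with planted antagonistic fold changes, and a ground-truth
# manifest used as the oracle by the test suite.
#
# NB parameterization throughout: mean mu and dispersion alpha with
# variance = mu + alpha * mu^2; alpha = 0 degenerates to Poisson.

#' Synthetic dataset configuration
#'
#' Defaults state the emulated world: a 2 accessions x 2 tissues x
#' 6 time points x 3 replicates design (72 samples), arm-switch loci with
#' true 5p proportions 0.9 vs 0.1 between the two tissues, NB depth with
#' mean 400 and dispersion 0.05 per hairpin, and antagonistic
#' miRNA:lncRNA pairs planted at |log2FC| = 2.
#'
#' @param n_hairpins number of hairpin loci (default 200).
#' @param n_switch_loci hairpins with a planted dominance shift (default 10).
#' @param arm_prop_a,arm_prop_b true 5p read proportion at switch loci in
#'   the first and second tissue (defaults 0.9 and 0.1); other loci sit at
#'   0.5 everywhere.
#' @param nb_mean,nb_dispersion NB depth per hairpin per sample.
#' @param n_replicates biological replicates per design cell (default 3).
#' @param accessions,tissues,time_points_h design axes (defaults C08/W05,
#'   root/leaf, 0,1,2,4,24,48 h).
#' @param n_lncrnas,n_interacting_pairs lncRNA pool and planted interacting
#'   pairs (defaults 100 and 50).
#' @param planted_lfc planted antagonistic |log2FC| (default 2).
#' @param planted_penalty target duplex penalty of planted sites, reached
#'   with G:U wobbles outside the seed (default 0: exact complement).
#' @param seq_error_rate per-base substitution rate in simulated reads
#'   (default 0).
#' @param adapter3p 3' adapter appended to reads (default: the standard
#'   Illumina TruSeq small RNA adapter).
#' @param seed integer master seed; each generator derives an independent
#'   stream from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_hairpins = 200L, n_switch_loci = 10L,
                       arm_prop_a = 0.9, arm_prop_b = 0.1,
                       nb_mean = 400, nb_dispersion = 0.05,
                       n_replicates = 3L,
                       accessions = c("C08", "W05"),
                       tissues = c("root", "leaf"),
                       time_points_h = c(0, 1, 2, 4, 24, 48),
                       n_lncrnas = 100L, n_interacting_pairs = 50L,
                       planted_lfc = 2.0, planted_penalty = 0.0,
                       seq_error_rate = 0.0,
                       adapter3p = "UGGAAUUCUCGGGUGCCAAGG",
                       seed = 1L) {
  stopifnot(n_switch_loci <= n_hairpins, n_interacting_pairs <= n_lncrnas,
            arm_prop_a > 0, arm_prop_a < 1, arm_prop_b > 0, arm_prop_b < 1,
            nb_mean > 0, nb_dispersion >= 0, seq_error_rate >= 0,
            seq_error_rate < 1, n_replicates >= 1, length(tissues) >= 1)
  structure(as.list(environment()), class = "sim_config")
}

rng_scope <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed %% .Machine$integer.max)
  expr
}

random_rna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = ""),
    character(1))
}

rnb <- function(n, mean, dispersion) {
  if (dispersion == 0) rpois(n, mean) else rnbinom(n, mu = mean, size = 1 / dispersion)
}

#' Generate hairpin loci with annotated arms
#'
#' Each hairpin is a random 21-nt 5p arm, a random 12-18 nt loop, and a
#' 21-nt 3p arm derived as the reverse complement of the 5p arm with two
#' random point mutations (hairpin-like; folding is irrelevant here).
#'
#' @param cfg [sim_config()].
#' @return list with `loci` (hairpin loci data.frame, 0-based half-open arm
#'   intervals), `fasta` (named hairpin sequences) and `matures` (named
#'   mature arm sequences).
#' @export
generate_hairpins <- function(cfg) {
  rng_scope(cfg$seed + 101L, {
    n <- cfg$n_hairpins
    ids <- sprintf("hp%04d", seq_len(n))
    arm5 <- random_rna(n, 21L)
    loops <- random_rna(n, 30L)  # trimmed per-locus below
    looplen <- sample(12:18, n, replace = TRUE)
    arm3 <- vapply(arm5, function(a) {
      s <- strsplit(revcomp_rna(a), "", fixed = TRUE)[[1]]
      at <- sample(seq_along(s), 2L)
      for (p in at) s[p] <- sample(setdiff(c("A", "C", "G", "U"), s[p]), 1L)
      paste(s, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    seqs <- paste0(arm5, substr(loops, 1L, looplen), arm3)
    loci <- data.frame(
      hairpin_id = ids, sequence = seqs,
      arm5p_start = rep(0L, n), arm5p_end = rep(21L, n),
      arm3p_start = 21L + looplen, arm3p_end = nchar(seqs),
      mature5p_id = paste0(ids, "-5p", recycle0 = TRUE),
      mature3p_id = paste0(ids, "-3p", recycle0 = TRUE),
      stringsAsFactors = FALSE
    )
    matures <- setNames(c(arm5, arm3), c(loci$mature5p_id, loci$mature3p_id))
    list(loci = loci, fasta = setNames(seqs, ids), matures = matures)
  })
}

#' Build the full sample sheet for a configuration
#'
#' @param cfg [sim_config()].
#' @return sample sheet data.frame (`sample_id`, `accession`, `tissue`,
#'   `time_h`, `replicate`), one row per library.
#' @export
build_design <- function(cfg) {
  g <- expand.grid(replicate = seq_len(cfg$n_replicates),
                   time_h = cfg$time_points_h,
                   tissue = cfg$tissues,
                   accession = cfg$accessions,
                   stringsAsFactors = FALSE)
  g <- g[, c("accession", "tissue", "time_h", "replicate")]
  g$sample_id <- sprintf("%s_%s_t%g_r%d", g$accession, g$tissue, g$time_h, g$replicate)
  g[, c("sample_id", "accession", "tissue", "time_h", "replicate")]
}

# True 5p proportion of hairpin i in a given tissue under cfg.
true_arm_prop <- function(cfg, hairpin_index, tissue) {
  if (hairpin_index <= cfg$n_switch_loci && length(cfg$tissues) >= 2L) {
    if (tissue == cfg$tissues[1]) cfg$arm_prop_a else cfg$arm_prop_b
  } else 0.5
}

#' Simulate arm-derived reads and the true arm count table
#'
#' Per sample and hairpin the total depth is NB(`nb_mean`, `nb_dispersion`);
#' reads split between arms by the hairpin's true 5p proportion for that
#' sample's tissue (`arm_prop_a` / `arm_prop_b` at switch loci, 0.5
#' elsewhere). Reads are exact arm sequences with per-base substitution
#' errors at `seq_error_rate`, the 3' adapter appended, and constant
#' Phred 35 qualities.
#'
#' @param hp output of [generate_hairpins()].
#' @param cfg [sim_config()].
#' @param design sample sheet (default [build_design(cfg)]).
#' @param out_dir if non-NULL, one FASTQ per sample is written under
#'   `out_dir/reads/` and the returned design gains a `fastq_path` column.
#' @param counts_only skip read construction entirely (truth counts only).
#' @return list with `arm_counts` (true table: hairpin_id, sample_id,
#'   count5p, count3p, unassigned = 0), `design`, and `switch_truth`
#'   (planted switch loci with their tissue-level dominance labels).
#' @export
simulate_arm_reads <- function(hp, cfg, design = build_design(cfg),
                               out_dir = NULL, counts_only = FALSE) {
  rng_scope(cfg$seed + 202L, {
    loci <- hp$loci
    n <- nrow(loci)
    tabs <- vector("list", nrow(design))
    if (!is.null(out_dir) && !counts_only)
      dir.create(file.path(out_dir, "reads"), recursive = TRUE, showWarnings = FALSE)
    fastq_paths <- character(nrow(design))
    for (s in seq_len(nrow(design))) {
      tissue <- design$tissue[s]
      total <- rnb(n, cfg$nb_mean, cfg$nb_dispersion)
      prop <- vapply(seq_len(n), true_arm_prop, numeric(1),
                     cfg = cfg, tissue = tissue)
      total <- as.integer(total)
      c5 <- as.integer(rbinom(n, total, prop))
      c3 <- total - c5
      tabs[[s]] <- data.frame(hairpin_id = loci$hairpin_id,
                              sample_id = rep(design$sample_id[s], n),
                              count5p = c5, count3p = c3,
                              unassigned = rep(0L, n),
                              stringsAsFactors = FALSE)
      if (!counts_only && !is.null(out_dir)) {
        arm5 <- substr(loci$sequence, loci$arm5p_start + 1L, loci$arm5p_end)
        arm3 <- substr(loci$sequence, loci$arm3p_start + 1L, loci$arm3p_end)
        seqs <- c(rep(arm5, c5), rep(arm3, c3))
        src <- c(rep(loci$hairpin_id, c5), rep(loci$hairpin_id, c3))
        arm <- c(rep("5p", sum(c5)), rep("3p", sum(c3)))
        if (cfg$seq_error_rate > 0 && length(seqs)) {
          seqs <- vapply(seqs, function(x) {
            ch <- strsplit(x, "", fixed = TRUE)[[1]]
            hit <- which(runif(length(ch)) < cfg$seq_error_rate)
            for (p in hit) ch[p] <- sample(setdiff(c("A", "C", "G", "U"), ch[p]), 1L)
            paste(ch, collapse = "")
          }, character(1), USE.NAMES = FALSE)
        }
        full <- paste0(seqs, cfg$adapter3p, recycle0 = TRUE)
        reads <- data.frame(
          id = sprintf("%s_%s_%s_%06d", rep(design$sample_id[s], length(full)),
                       src, arm, seq_along(full)),
          seq = full,
          qual = strrep(rawToChar(as.raw(33L + 35L)), nchar(full)),
          stringsAsFactors = FALSE
        )
        fq <- file.path(out_dir, "reads", paste0(design$sample_id[s], ".fastq"))
        write_fastq(reads, fq)
        fastq_paths[s] <- fq
      }
    }
    if (!counts_only && !is.null(out_dir)) design$fastq_path <- fastq_paths
    switch_truth <- if (cfg$n_switch_loci > 0L && length(cfg$tissues) >= 2L) {
      data.frame(
        hairpin_id = loci$hairpin_id[seq_len(cfg$n_switch_loci)],
        tissue_a = cfg$tissues[1], tissue_b = cfg$tissues[2],
        dominance_a = dominance_from_prop(cfg$arm_prop_a),
        dominance_b = dominance_from_prop(cfg$arm_prop_b),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(hairpin_id = character(), tissue_a = character(),
                 tissue_b = character(), dominance_a = character(),
                 dominance_b = character(), stringsAsFactors = FALSE)
    }
    list(arm_counts = do.call(rbind, c(tabs, make.row.names = FALSE)),
         design = design, switch_truth = switch_truth)
  })
}

# Dominance label implied by a true 5p proportion under default cutoffs.
dominance_from_prop <- function(prop, params = switch_params()) {
  if (prop > params$high_cut) "dominant5p"
  else if (prop < params$low_cut) "dominant3p"
  else "unclassified"
}

#' Generate lncRNA sequences with planted miRNA-complementary sites
#'
#' Interacting lncRNAs (the first `n_interacting_pairs`) are 400-800 nt
#' random sequences carrying the reverse complement of their partner miRNA
#' at a recorded position, optionally degraded with G:U wobbles outside the
#' seed to reach `planted_penalty`; the remainder carry no insertion.
#'
#' @param cfg [sim_config()].
#' @param mirna_sequences named character vector of mature miRNA sequences;
#'   partners are taken cyclically.
#' @param params [duplex_params()] used to place wobbles outside the seed.
#' @return list with `fasta` (named lncRNA sequences) and `planted`
#'   (data.frame: mirna_id, lncrna_id, start, end, planted_penalty).
#' @export
generate_lncrnas_with_sites <- function(cfg, mirna_sequences,
                                        params = duplex_params()) {
  rng_scope(cfg$seed + 303L, {
    n <- cfg$n_lncrnas
    k <- cfg$n_interacting_pairs
    ids <- sprintf("lnc%04d", seq_len(n))
    lens <- sample(400:800, n, replace = TRUE)
    seqs <- vapply(lens, function(l)
      paste(sample(c("A", "C", "G", "U"), l, replace = TRUE), collapse = ""),
      character(1))
    planted <- list()
    for (i in seq_len(k)) {
      mi <- ((i - 1L) %% length(mirna_sequences)) + 1L
      m <- mirna_sequences[[mi]]
      L <- nchar(m)
      site <- site_with_penalty(m, cfg$planted_penalty, params)
      pos <- sample(seq_len(lens[i] - L + 1L), 1L)  # 1-based insert position
      seqs[i] <- paste0(substr(seqs[i], 1L, pos - 1L), site$site,
                        substr(seqs[i], pos + L, lens[i]))
      planted[[i]] <- data.frame(
        mirna_id = names(mirna_sequences)[mi], lncrna_id = ids[i],
        start = pos - 1L, end = pos - 1L + L,
        planted_penalty = site$penalty, stringsAsFactors = FALSE
      )
    }
    list(
      fasta = setNames(seqs, ids),
      planted = if (length(planted)) do.call(rbind, c(planted, make.row.names = FALSE))
      else data.frame(mirna_id = character(), lncrna_id = character(),
                      start = integer(), end = integer(),
                      planted_penalty = numeric(), stringsAsFactors = FALSE)
    )
  })
}

# Build a target site for a miRNA: its reverse complement, degraded with
# G:U wobbles at non-seed positions until the requested penalty is reached.
# Only wobble-sized increments are available, so the achieved penalty is
# min(requested, available) rounded down to a multiple of wobble_penalty.
site_with_penalty <- function(mirna, penalty, params = duplex_params()) {
  m <- strsplit(normalize_rna(mirna), "", fixed = TRUE)[[1]]
  L <- length(m)
  site <- strsplit(revcomp_rna(mirna), "", fixed = TRUE)[[1]]
  achieved <- 0
  if (penalty > 0) {
    seed <- seq(params$seed_start, params$seed_end)
    cand <- setdiff(which(m %in% c("G", "U")), seed)
    cand <- sample(cand)
    for (i in cand) {
      if (achieved + params$wobble_penalty > penalty + 1e-9) break
      j <- L - i + 1L  # site position pairing miRNA position i
      site[j] <- if (m[i] == "G") "U" else "G"
      achieved <- achieved + params$wobble_penalty
    }
  }
  list(site = paste(site, collapse = ""), penalty = achieved)
}

#' Simulate expression matrices with planted antagonistic pairs
#'
#' NB counts at baseline `nb_mean` for every miRNA and lncRNA feature over
#' the full design; for each planted pair, in the planted contrast the
#' miRNA mean is multiplied by `2^(-planted_lfc)` and the lncRNA mean by
#' `2^(planted_lfc)` (direction alternating between pairs, recorded in the
#' manifest). Library sizes are the column totals inflated by 25% (counted
#' features never hold every retained read).
#'
#' @param cfg [sim_config()].
#' @param mirna_ids,lncrna_ids feature ids; planted pair `i` links
#'   `mirna_ids[i]` with `lncrna_ids[i]`.
#' @param design sample sheet (default [build_design(cfg)]).
#' @return list with `mirna` and `lncrna` [count_matrix()] objects,
#'   `contrast` (list: group_a, group_b sample ids and labels), and
#'   `de_truth` (feature_id, contrast, direction, true_lfc).
#' @export
simulate_expression <- function(cfg, mirna_ids, lncrna_ids,
                                design = build_design(cfg)) {
  rng_scope(cfg$seed + 404L, {
    k <- cfg$n_interacting_pairs
    stopifnot(k <= length(mirna_ids), k <= length(lncrna_ids))
    tissue <- if (length(cfg$tissues) >= 2L) cfg$tissues[2] else cfg$tissues[1]
    tp <- cfg$time_points_h
    ta <- if (4 %in% tp && 24 %in% tp) 4 else tp[1]
    tb <- if (4 %in% tp && 24 %in% tp) 24 else tp[min(2L, length(tp))]
    acc <- cfg$accessions[1]
    in_group <- function(t) design$sample_id[design$accession == acc &
                                               design$tissue == tissue &
                                               design$time_h == t]
    ga <- in_group(ta)
    gb <- in_group(tb)
    label_a <- condition_label(acc, tissue, ta)
    label_b <- condition_label(acc, tissue, tb)
    contrast <- paste(label_a, "vs", label_b)

    gen <- function(ids, planted_dir) {
      mu <- matrix(cfg$nb_mean, nrow = length(ids), ncol = nrow(design),
                   dimnames = list(ids, design$sample_id))
      for (i in seq_len(k)) {
        dirn <- planted_dir[i]
        mu[ids[i], gb] <- cfg$nb_mean * 2^(ifelse(dirn == "up", 1, -1) * cfg$planted_lfc)
      }
      counts <- matrix(rnb(length(mu), as.vector(mu), cfg$nb_dispersion),
                       nrow = nrow(mu), dimnames = dimnames(mu))
      # library size is the total retained reads of the library, which a
      # handful of planted features cannot move: a fixed nominal size
      # avoids the composition bias that column-sum normalization would
      # introduce at desk-scale feature counts
      libsize <- max(1, round(length(ids) * cfg$nb_mean * 1.25))
      count_matrix(counts, setNames(rep(libsize, ncol(counts)),
                                    colnames(counts)))
    }
    # alternate which side goes up so both antagonism signs are exercised
    mirna_dir <- ifelse(seq_len(k) %% 2L == 1L, "down", "up")
    lncrna_dir <- ifelse(mirna_dir == "down", "up", "down")
    mirna <- gen(mirna_ids, mirna_dir)
    lncrna <- gen(lncrna_ids, lncrna_dir)
    de_truth <- rbind(
      data.frame(feature_id = mirna_ids[seq_len(k)], contrast = contrast,
                 direction = mirna_dir,
                 true_lfc = ifelse(mirna_dir == "up", 1, -1) * cfg$planted_lfc,
                 stringsAsFactors = FALSE),
      data.frame(feature_id = lncrna_ids[seq_len(k)], contrast = contrast,
                 direction = lncrna_dir,
                 true_lfc = ifelse(lncrna_dir == "up", 1, -1) * cfg$planted_lfc,
                 stringsAsFactors = FALSE)
    )
    list(mirna = mirna, lncrna = lncrna,
         contrast = list(group_a = ga, group_b = gb,
                         label_a = label_a, label_b = label_b),
         de_truth = de_truth)
  })
}

#' Write / read the ground-truth manifest (JSON)
#'
#' @param manifest list with `switch_loci`, `de_features` and
#'   `interacting_pairs` data.frames.
#' @param path JSON file.
#' @return the path (write) or the manifest list (read); the round trip is
#'   an identity.
#' @export
write_truth_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth_manifest
#' @export
read_truth_manifest <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lapply(x, function(el) if (is.list(el) && !is.data.frame(el))
    as.data.frame(el, stringsAsFactors = FALSE) else el)
}

#' Simulate a complete dataset on disk
#'
#' Emits `hairpins.fa`, `arms.gff3`, `reads/*.fastq`, `samples.tsv`,
#' `lncrna.fa`, `mirna.fa`, `counts_mirna.tsv`, `abund_lncrna.tsv` and
#' `truth.json` under `out_dir`.
#'
#' @param cfg [sim_config()].
#' @param out_dir output directory (created).
#' @param emit_fastq also simulate per-sample FASTQ reads (default TRUE;
#'   the expression matrices are generated either way).
#' @return invisible list of the in-memory artifacts (hairpins, reads
#'   truth, lncRNAs, expression, manifest, paths).
#' @export
simulate_dataset <- function(cfg, out_dir, emit_fastq = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hp <- generate_hairpins(cfg)
  write_fasta(hp$fasta, file.path(out_dir, "hairpins.fa"))
  write_arm_gff(hp$loci, file.path(out_dir, "arms.gff3"))
  reads <- simulate_arm_reads(hp, cfg,
                              out_dir = if (emit_fastq) out_dir else NULL,
                              counts_only = !emit_fastq)
  design <- reads$design
  if (is.null(design$fastq_path)) design$fastq_path <- ""
  write_sample_sheet(design, file.path(out_dir, "samples.tsv"))

  mirnas <- hp$matures[hp$loci$mature5p_id]  # 5p arms act as the miRNA pool
  lnc <- generate_lncrnas_with_sites(cfg, mirnas)
  write_fasta(mirnas, file.path(out_dir, "mirna.fa"))
  write_fasta(lnc$fasta, file.path(out_dir, "lncrna.fa"))

  expr <- simulate_expression(cfg, names(mirnas), names(lnc$fasta))
  write_count_matrix(expr$mirna, file.path(out_dir, "counts_mirna.tsv"))
  write_count_matrix(expr$lncrna, file.path(out_dir, "abund_lncrna.tsv"))

  manifest <- list(
    switch_loci = reads$switch_truth,
    de_features = expr$de_truth,
    interacting_pairs = lnc$planted
  )
  write_truth_manifest(manifest, file.path(out_dir, "truth.json"))
  invisible(list(hairpins = hp, reads = reads, lncrnas = lnc, expr = expr,
                 manifest = manifest, out_dir = out_dir))
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson shuffle: returns a random sequence with exactly the
#' same dinucleotide (and hence mononucleotide) composition, used to
#' estimate false-site rates of the duplex scanner.
#'
#' @param seq a single sequence.
#' @return shuffled sequence of the same length.
#' @export
dinucleotide_shuffle <- function(seq) {
  s <- strsplit(normalize_rna(seq), "", fixed = TRUE)[[1]]
  n <- length(s)
  if (n < 3L) return(paste(s, collapse = ""))
  verts <- unique(s)
  edges <- split(s[-1], factor(s[-n], levels = verts))
  last <- s[n]
  repeat {
    pick <- lapply(verts, function(v) {
      e <- edges[[v]]
      if (v == last || !length(e)) NA_character_ else e[sample.int(length(e), 1L)]
    })
    names(pick) <- verts
    reaches <- vapply(verts, function(v) {
      seen <- character(0)
      while (v != last && !(v %in% seen) && !is.na(pick[[v]])) {
        seen <- c(seen, v)
        v <- pick[[v]]
      }
      v == last
    }, logical(1))
    if (all(reaches | vapply(verts, function(v) !length(edges[[v]]), logical(1))))
      break
  }
  ordered <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (!length(e)) return(e)
    if (v == last) return(sample(e))
    # remove one instance of the chosen last edge, shuffle the rest, append it
    idx <- which(e == pick[[v]])[1]
    c(sample(e[-idx]), e[idx])
  })
  names(ordered) <- verts
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- s[1]
  cur <- s[1]
  for (i in 2:n) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}
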