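# Orchestration: simulate -> trim -> quantify -> switch -> de -> interact,
# with a run report and end-to-end determinism under a fixed seed.

default_run_config <- function() {
  list(
    seed = 1,
    emit_fastq = TRUE,
    sim = list(n_hairpins = 40, n_switch_loci = 4, nb_mean = 400,
               nb_dispersion = 0.05, n_replicates = 3,
               accessions = "C08", tissues = c("root", "leaf"),
               time_points_h = c(4, 24), n_lncrnas = 20,
               n_interacting_pairs = 6),
    switch = list(min_count = 50, low_cut = 0.3, high_cut = 0.7),
    de = list(min_cpm = 50, min_abs_log2fc = 1, max_fdr = 0.05),
    duplex = list(max_total_penalty = 4.0)
  )
}

validate_run_config <- function(cfg) {
  known <- c("seed", "emit_fastq", "sim", "switch", "de", "duplex")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop("unknown config key(s): ", paste(extra, collapse = ", "))
  checks <- list(sim = sim_config, switch = switch_params, de = de_params,
                 duplex = duplex_params)
  for (sec in names(checks)) {
    if (is.null(cfg[[sec]])) next
    bad <- setdiff(names(cfg[[sec]]), names(formals(checks[[sec]])))
    if (length(bad))
      stop("unknown key(s) in [", sec, "]: ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(override[[k]]) && is.list(base[[k]]))
      merge_config(base[[k]], override[[k]]) else override[[k]]
  }
  base
}

#' Run the full synthetic pipeline
#'
#' Simulates a dataset, trims and QC-filters the reads, quantifies hairpin
#' arms, calls arm switches, screens the planted contrast for differential
#' expression of miRNAs and lncRNAs, scans DE candidates for duplex sites,
#' and screens for antagonistic interactions. Any stage failure aborts;
#' re-running with an identical config produces byte-identical result
#' tables.
#'
#' @param config path to an INI config (sections `[sim]`, `[switch]`,
#'   `[de]`, `[duplex]`; top-level `seed`, `emit_fastq`) or an equivalent
#'   nested list. Unknown keys are rejected before any stage runs.
#' @param out_dir output directory; receives `sim/`, `armcounts.tsv`,
#'   `switches.tsv`, `de.tsv`, `de_lncrna.tsv`, `interactions.tsv` and
#'   `report.json`.
#' @return the run report (invisibly): per-stage outputs, record counts,
#'   wall-clock seconds, package version and seed, plus a truth-recovery
#'   summary (`switches_found` / `switches_planted`, `pairs_found` /
#'   `pairs_planted`).
#' @export
run_all <- function(config = list(), out_dir) {
  if (is.character(config)) config <- read_config(config)
  cfg <- merge_config(default_run_config(), config)
  validate_run_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(version = as.character(packageVersion("armflip")),
                 seed = cfg$seed, stages = list())
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    report$stages[[name]] <<- c(value$meta,
                                list(seconds = round(proc.time()[["elapsed"]] - t0, 3)))
    value$out
  }

  simc <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
  swp <- do.call(switch_params, cfg$switch)
  dep <- do.call(de_params, cfg$de)
  dup <- do.call(duplex_params, cfg$duplex)

  sim <- stage("simulate", {
    s <- simulate_dataset(simc, file.path(out_dir, "sim"),
                          emit_fastq = isTRUE(cfg$emit_fastq))
    list(out = s, meta = list(hairpins = nrow(s$hairpins$loci),
                              samples = nrow(s$reads$design),
                              out_dir = s$out_dir))
  })

  arm_counts <- stage("quantify", {
    if (isTRUE(cfg$emit_fastq)) {
      fp <- read_filter_params(adapter3p = simc$adapter3p)
      tabs <- lapply(seq_len(nrow(sim$reads$design)), function(s) {
        rd <- read_fastq(sim$reads$design$fastq_path[s])
        rd <- trim_adapter(rd, fp$adapter3p)
        rd <- filter_reads(rd, fp)$kept
        tab <- quantify_arms(rd, sim$hairpins$loci)
        tab$sample_id <- sim$reads$design$sample_id[s]
        tab[, c("hairpin_id", "sample_id", "count5p", "count3p", "unassigned")]
      })
      tab <- do.call(rbind, c(tabs, make.row.names = FALSE))
    } else {
      tab <- sim$reads$arm_counts
    }
    path <- file.path(out_dir, "armcounts.tsv")
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    list(out = tab, meta = list(rows = nrow(tab), path = path))
  })

  switches <- stage("switch", {
    prof <- omega_profiles(arm_counts, swp)
    sw <- call_arm_switches(prof, sim$reads$design, swp)
    path <- file.path(out_dir, "switches.tsv")
    write.table(sw, path, sep = "\t", quote = FALSE, row.names = FALSE)
    list(out = sw, meta = list(calls = nrow(sw), path = path))
  })

  de <- stage("de", {
    ct <- sim$expr$contrast
    md <- screen_contrast(sim$expr$mirna, ct$group_a, ct$group_b, dep,
                          group_labels = c(ct$label_a, ct$label_b))
    ld <- screen_contrast(sim$expr$lncrna, ct$group_a, ct$group_b,
                          de_params(min_cpm = 0,
                                    min_abs_log2fc = dep$min_abs_log2fc,
                                    max_fdr = dep$max_fdr,
                                    pseudocount = dep$pseudocount,
                                    strict = dep$strict),
                          group_labels = c(ct$label_a, ct$label_b))
    write.table(md, file.path(out_dir, "de.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(ld, file.path(out_dir, "de_lncrna.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(out = list(mirna = md, lncrna = ld),
         meta = list(mirna_tested = sum(md$cpm_pass),
                     mirna_events = sum(md$direction != "ns"),
                     lncrna_events = sum(ld$direction != "ns"),
                     path = file.path(out_dir, "de.tsv")))
  })

  interactions <- stage("interact", {
    # scan only DE candidates for sites (the screen requires both criteria,
    # so non-DE features can never yield a call)
    mir_cand <- de$mirna$feature_id[de$mirna$direction != "ns"]
    lnc_cand <- de$lncrna$feature_id[de$lncrna$direction != "ns"]
    mirnas <- sim$hairpins$matures[intersect(mir_cand, names(sim$hairpins$matures))]
    lncs <- sim$lncrnas$fasta[intersect(lnc_cand, names(sim$lncrnas$fasta))]
    sites <- scan_duplex_pairs(mirnas, lncs, dup)
    calls <- screen_interactions(de$mirna, de$lncrna, sites)
    path <- file.path(out_dir, "interactions.tsv")
    write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
    list(out = calls, meta = list(sites = nrow(sites), calls = nrow(calls),
                                  path = path))
  })

  truth <- sim$manifest
  report$recovery <- list(
    switches_planted = nrow(truth$switch_loci),
    switches_found = length(intersect(unique(switches$hairpin_id),
                                      truth$switch_loci$hairpin_id)),
    pairs_planted = nrow(truth$interacting_pairs),
    pairs_found = nrow(unique(merge(
      interactions[, c("mirna_id", "lncrna_id")],
      truth$interacting_pairs[, c("mirna_id", "lncrna_id")])))
  )
  for (st in names(report$stages)) {
    p <- report$stages[[st]]$path
    if (!is.null(p) && (!file.exists(p) || file.size(p) == 0))
      stop("stage '", st, "' declared missing/empty output: ", p)
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("switches found/planted: %d/%d; pairs found/planted: %d/%d",
                  report$recovery$switches_found, report$recovery$switches_planted,
                  report$recovery$pairs_found, report$recovery$pairs_planted))
  invisible(report)
}
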