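plant_site <- function(mirna, left = 60, right = 60, site = revcomp_rna(mirna)) {
  set.seed(nchar(site) + left)
  paste0(rand_rna(left), site, rand_rna(right))
}

test_that("perfect complements are found with penalty zero at the interval", {
  set.seed(101)
  m <- rand_rna(21)
  target <- plant_site(m, left = 50, right = 40)
  sites <- find_duplex_sites(m, target)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$start, 50L)
  expect_equal(sites$end, 71L)
  expect_equal(sites$penalty, 0)
  expect_equal(sites$aln_bars, strrep("|", 21))
  # miRNA line is reported 3'->5'
  expect_equal(sites$aln_mirna,
               paste(rev(strsplit(m, "")[[1]]), collapse = ""))

  expect_error(find_duplex_sites(rand_rna(10), target), "16, 30")
  expect_error(find_duplex_sites(m, rand_rna(10)), "shorter")
})

test_that("random targets without complementary windows yield no sites", {
  set.seed(202)
  hits <- vapply(1:20, function(i) {
    nrow(find_duplex_sites(rand_rna(21), rand_rna(500)))
  }, integer(1))
  # seed-fixed: a random 500-mer essentially never carries a 7-mer exact
  # seed match plus a near-perfect remainder
  expect_lte(sum(hits > 0), 1L)
})

test_that("a single wobble outside the seed scores exactly wobble_penalty", {
  set.seed(303)
  params <- duplex_params()
  repeat {  # need a miRNA with G or U at position 12 (outside seed)
    m <- rand_rna(21)
    if (substr(m, 12, 12) %in% c("G", "U")) break
  }
  site <- strsplit(revcomp_rna(m), "", fixed = TRUE)[[1]]
  j <- 21 - 12 + 1  # site column pairing miRNA position 12
  site[j] <- if (substr(m, 12, 12) == "G") "U" else "G"
  target <- plant_site(m, site = paste(site, collapse = ""))
  sites <- find_duplex_sites(m, target, params)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$penalty, params$wobble_penalty)
  expect_equal(sites$seed_mismatch, 0L)
  # oracle: exhaustive ungapped window rescoring finds the same best window
  orc <- oracle_scan_ungapped(m, target, params)
  best <- orc[which.min(orc$penalty), ]
  expect_equal(best$start0, sites$start)
  expect_equal(best$penalty, sites$penalty)
})

test_that("reported alignments rescore to their reported penalty", {
  set.seed(404)
  params <- duplex_params()
  n_checked <- 0L
  for (i in 1:30) {
    m <- rand_rna(sample(19:24, 1))
    # plant a degraded site: random mutations outside the seed
    site <- strsplit(revcomp_rna(m), "", fixed = TRUE)[[1]]
    L <- nchar(m)
    nmut <- sample(0:2, 1)
    muts <- sample(setdiff(seq_len(L), (L - params$seed_end + 1):(L - params$seed_start + 1)),
                   nmut)
    for (j in muts) site[j] <- sample(setdiff(ALPHA_RNA, site[j]), 1)
    target <- plant_site(m, site = paste(site, collapse = ""))
    sites <- find_duplex_sites(m, target, params)
    for (k in seq_len(nrow(sites))) {
      expect_equal(oracle_rescore_alignment(sites$aln_mirna[k], sites$aln_bars[k],
                                            sites$aln_target[k], params),
                   sites$penalty[k], tolerance = 1e-12)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 20L)
})

test_that("penalty of Watson-Crick sites is invariant under A<->U, G<->C relabeling", {
  set.seed(505)
  for (i in 1:10) {
    m <- rand_rna(21)
    target <- plant_site(m)
    s1 <- find_duplex_sites(m, target)
    s2 <- find_duplex_sites(chartr("AUGC", "UACG", m),
                            chartr("AUGC", "UACG", target))
    expect_equal(s1$penalty[which(s1$start == 60)],
                 s2$penalty[which(s2$start == 60)])
  }
})

test_that("gapped sites are found with gap penalty, gap confined outside the seed", {
  set.seed(606)
  params <- duplex_params()
  m <- rand_rna(21)
  site <- strsplit(revcomp_rna(m), "", fixed = TRUE)[[1]]
  # delete the target base pairing miRNA position 12: a miRNA bulge
  target <- plant_site(m, site = paste(site[-(21 - 12 + 1)], collapse = ""))
  sites <- find_duplex_sites(m, target, params)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$penalty, params$gap_penalty)
  expect_equal(sites$end - sites$start, 20L)  # window one shorter
  expect_true(grepl("-", sites$aln_target))
  # and a target bulge: insert a base between positions pairing 11 and 12
  ins <- append(site, "A", after = 21 - 12 + 1)
  target2 <- plant_site(m, site = paste(ins, collapse = ""))
  sites2 <- find_duplex_sites(m, target2, params)
  expect_equal(sites2$penalty, params$gap_penalty)
  expect_equal(sites2$end - sites2$start, 22L)
  expect_true(grepl("-", sites2$aln_mirna))
})

de_stub <- function(features, directions, ga = "condA", gb = "condB") {
  data.frame(feature_id = features, group_a = ga, group_b = gb,
             mean_cpm_a = 100, mean_cpm_b = 100, log2fc = 0, pvalue = 0.01,
             fdr = 0.01, cpm_pass = TRUE, direction = directions,
             stringsAsFactors = FALSE)
}

site_stub <- function(mirna_id, target_id) {
  data.frame(mirna_id = mirna_id, target_id = target_id, start = 10L,
             end = 31L, penalty = 0, seed_mismatch = 0L,
             aln_mirna = "x", aln_bars = "x", aln_target = "x",
             stringsAsFactors = FALSE)
}

test_that("interaction screen requires a site plus antagonistic directions", {
  sites <- site_stub("miR1", "lnc1")
  # miRNA down + lncRNA up in the same contrast -> call
  call <- screen_interactions(de_stub("miR1", "down"), de_stub("lnc1", "up"), sites)
  expect_equal(nrow(call), 1L)
  expect_equal(call$mirna_direction, "down")
  expect_equal(call$lncrna_direction, "up")

  # equal directions -> no call
  expect_equal(nrow(screen_interactions(de_stub("miR1", "up"),
                                        de_stub("lnc1", "up"), sites)), 0L)
  # ns on either side -> no call
  expect_equal(nrow(screen_interactions(de_stub("miR1", "ns"),
                                        de_stub("lnc1", "up"), sites)), 0L)
  # no site -> no call even with opposite directions
  expect_equal(nrow(screen_interactions(de_stub("miR1", "down"),
                                        de_stub("lnc1", "up"),
                                        site_stub("miR1", "lnc999"))), 0L)
  # contrast label mismatch is a hard error
  expect_error(screen_interactions(de_stub("miR1", "down"),
                                   de_stub("lnc1", "up", ga = "other"), sites),
               "contrast label mismatch")
})

test_that("one call per (pair, contrast) across multiple contrasts", {
  sites <- site_stub("miR1", "lnc1")
  mde <- rbind(de_stub("miR1", "down"),
               de_stub("miR1", "up", ga = "condC", gb = "condD"))
  lde <- rbind(de_stub("lnc1", "up"),
               de_stub("lnc1", "down", ga = "condC", gb = "condD"))
  calls <- screen_interactions(mde, lde, sites)
  expect_equal(nrow(calls), 2L)
  expect_setequal(calls$contrast, c("condA vs condB", "condC vs condD"))
})

test_that("predict_targets scans per region and labels sites", {
  set.seed(707)
  m <- rand_rna(21)
  regions <- data.frame(
    region_id = c("g1.5utr", "g1.cds", "g1.3utr"),
    region_type = c("5UTR", "CDS", "3UTR"),
    sequence = c(rand_rna(100), rand_rna(300), plant_site(m, 40, 40)),
    stringsAsFactors = FALSE
  )
  hits <- predict_targets(m, regions)
  expect_equal(unique(hits$region_type), "3UTR")
  expect_equal(hits$penalty, 0)

  expect_equal(nrow(predict_targets(m, regions[0, ])), 0L)
  expect_error(predict_targets(m, rbind(regions, regions[1, ])),
               "duplicate region_id")
  bad <- regions; bad$region_type[1] <- "intron"
  expect_error(predict_targets(m, bad), "unknown region_type")
})
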