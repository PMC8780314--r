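test_that("omega definition, limits and properties", {
  expect_equal(compute_omega(100, 0), 1.0)
  expect_equal(compute_omega(30, 70), 0.3)
  expect_true(is.na(compute_omega(0, 0)))
  expect_error(compute_omega(-1, 5), "negative")

  set.seed(9)
  a <- sample(0:500, 200, replace = TRUE)
  b <- sample(0:500, 200, replace = TRUE)
  ok <- a + b > 0
  # complement symmetry and range
  expect_equal(compute_omega(a[ok], b[ok]) + compute_omega(b[ok], a[ok]),
               rep(1, sum(ok)))
  expect_true(all(compute_omega(a[ok], b[ok]) >= 0 &
                    compute_omega(a[ok], b[ok]) <= 1))
  # strictly increasing in count5p at fixed count3p > 0
  w <- compute_omega(0:50, 30)
  expect_true(all(diff(w) > 0))
})

test_that("dominance classification applies strict cuts and the count gate", {
  p <- switch_params()
  # the >50 gate is strict and applies to max(count5p, count3p)
  expect_equal(classify_dominance(compute_omega(25, 50), 25, 50, p), "insufficient")
  expect_equal(classify_dominance(compute_omega(50, 50), 50, 50, p), "insufficient")
  # one arm over 50 suffices ("either arm with absolute counts > 50")
  expect_equal(classify_dominance(compute_omega(25, 75), 25, 75, p), "dominant3p")
  expect_equal(classify_dominance(0.25, 100, 300, p), "dominant3p")
  expect_equal(classify_dominance(0.75, 300, 100, p), "dominant5p")
  # boundaries are strict: omega == 0.7 or == 0.3 stays unclassified
  expect_equal(classify_dominance(0.70, 700, 300, p), "unclassified")
  expect_equal(classify_dominance(0.30, 300, 700, p), "unclassified")

  # mirror property: swapping arms swaps the labels
  set.seed(21)
  a <- sample(0:1000, 300, replace = TRUE)
  b <- sample(0:1000, 300, replace = TRUE)
  d1 <- classify_dominance(compute_omega(a, b), a, b, p)
  d2 <- classify_dominance(compute_omega(b, a), b, a, p)
  swap <- c(dominant5p = "dominant3p", dominant3p = "dominant5p",
            unclassified = "unclassified", insufficient = "insufficient")
  expect_equal(unname(swap[d1]), d2)
})

test_that("quantify_arms assigns arm, loop and multi-arm reads correctly", {
  loci <- tiny_loci()
  arm5 <- substr(loci$sequence[1], 1, 21)
  arm3 <- substr(loci$sequence[1], 36, 56)
  loop <- substr(loci$sequence[1], 23, 34)  # fully inside the loop

  tab <- quantify_arms(c(arm5, arm5, arm3, loop), loci)
  expect_equal(tab$count5p, c(2L, 0L))
  expect_equal(tab$count3p, c(1L, 0L))
  expect_equal(tab$unassigned, c(1L, 0L))
  expect_equal(attr(tab, "unmapped"), 0L)

  # read matching nothing is unmapped, not unassigned
  tab2 <- quantify_arms(strrep("A", 21), loci)
  expect_equal(sum(tab2$count5p + tab2$count3p + tab2$unassigned), 0L)
  expect_equal(attr(tab2, "unmapped"), 1L)

  expect_error(quantify_arms(arm5, loci[0, ]), "empty hairpin")
})

test_that("quantify_arms matches a containment oracle on 700/300 draws", {
  loci <- tiny_loci(seed = 77)
  set.seed(1234)
  arm5 <- substr(loci$sequence[1], 1, 21)
  arm3 <- substr(loci$sequence[1], 36, 56)
  reads <- sample(c(rep(arm5, 700), rep(arm3, 300)))
  tab <- quantify_arms(reads, loci)
  expect_equal(tab$count5p[1], 700L)
  expect_equal(tab$count3p[1], 300L)
  # oracle: direct substring containment per read
  expect_equal(sum(vapply(reads, function(r)
    grepl(r, loci$sequence[1], fixed = TRUE) &&
      grepl(r, arm5, fixed = TRUE), logical(1))), 700L)
})

test_that("quantify_arms tolerates mismatches only up to max_mismatch", {
  loci <- tiny_loci()
  arm5 <- substr(loci$sequence[1], 1, 21)
  mutated <- arm5
  substr(mutated, 10, 10) <- setdiff(c("A", "C", "G", "U"),
                                     substr(arm5, 10, 10))[1]
  expect_equal(attr(quantify_arms(mutated, loci, max_mismatch = 0), "unmapped"), 1L)
  tab <- quantify_arms(mutated, loci, max_mismatch = 1)
  expect_equal(tab$count5p[1], 1L)
})

make_profiles <- function(omegas_by_cond, depth = 1000) {
  # omegas_by_cond: named list cond -> numeric omegas (one per replicate)
  rows <- list()
  design <- list()
  for (cn in names(omegas_by_cond)) {
    parts <- strsplit(cn, ":", fixed = TRUE)[[1]]
    for (r in seq_along(omegas_by_cond[[cn]])) {
      w <- omegas_by_cond[[cn]][r]
      sid <- paste0(cn, "_r", r)
      c5 <- round(depth * w); c3 <- depth - c5
      rows[[length(rows) + 1L]] <- data.frame(
        hairpin_id = "hp1", sample_id = sid, count5p = c5, count3p = c3,
        stringsAsFactors = FALSE)
      design[[length(design) + 1L]] <- data.frame(
        sample_id = sid, accession = parts[1], tissue = parts[2],
        time_h = as.numeric(sub("h$", "", parts[3])), replicate = r,
        stringsAsFactors = FALSE)
    }
  }
  list(profiles = omega_profiles(do.call(rbind, rows)),
       design = do.call(rbind, design))
}

test_that("switch calls require opposite, replicate-unanimous dominance", {
  # the root-5p vs leaf-3p pattern
  x <- make_profiles(list("C08:root:48h" = c(0.9, 0.85, 0.95),
                          "C08:leaf:48h" = c(0.1, 0.2, 0.15)))
  calls <- call_arm_switches(x$profiles, x$design)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$dominance_a, "dominant3p")  # leaf sorts before root
  expect_equal(calls$dominance_b, "dominant5p")
  expect_equal(calls$condition_a, "C08:leaf:48h")

  # same dominance on both sides: no call
  x2 <- make_profiles(list("C08:root:48h" = c(0.9, 0.85, 0.95),
                           "C08:leaf:48h" = c(0.8, 0.9, 0.95)))
  expect_equal(nrow(call_arm_switches(x2$profiles, x2$design)), 0L)

  # one unclassified replicate blocks the call under require_all_replicates
  x3 <- make_profiles(list("C08:root:48h" = c(0.9, 0.85, 0.5),
                           "C08:leaf:48h" = c(0.1, 0.2, 0.15)))
  expect_equal(nrow(call_arm_switches(x3$profiles, x3$design)), 0L)
  relaxed <- call_arm_switches(x3$profiles, x3$design,
                               switch_params(require_all_replicates = FALSE))
  expect_equal(nrow(relaxed), 1L)

  # an insufficient replicate likewise blocks
  x4 <- make_profiles(list("C08:root:48h" = c(0.9, 0.85, 0.95),
                           "C08:leaf:48h" = c(0.1, 0.2, 0.15)))
  x4$profiles$count5p[1] <- 20L; x4$profiles$count3p[1] <- 30L  # below the gate
  x4$profiles <- omega_profiles(x4$profiles)
  expect_equal(nrow(call_arm_switches(x4$profiles, x4$design)), 0L)
})

test_that("switch calling is symmetric under condition relabeling", {
  x <- make_profiles(list("C08:root:48h" = c(0.9, 0.85, 0.95),
                          "C08:leaf:48h" = c(0.1, 0.2, 0.15)))
  fwd <- call_arm_switches(x$profiles, x$design)
  # swap the tissue labels on both profiles and design: the same data with
  # condition names exchanged must swap dominance_a/dominance_b only
  swap_tissue <- function(v) c(root = "leaf", leaf = "root")[v]
  x$design$tissue <- unname(swap_tissue(x$design$tissue))
  rev_ <- call_arm_switches(x$profiles, x$design)
  expect_equal(rev_$dominance_a, fwd$dominance_b)
  expect_equal(rev_$dominance_b, fwd$dominance_a)
  expect_equal(rev_$omega_a, fwd$omega_b)
})

test_that("conditions in the design but absent from profiles are skipped with a warning", {
  x <- make_profiles(list("C08:root:48h" = c(0.9, 0.9, 0.9),
                          "C08:leaf:48h" = c(0.1, 0.1, 0.1)))
  extra <- data.frame(sample_id = "ghost", accession = "C08", tissue = "root",
                      time_h = 4, replicate = 1)
  design <- rbind(x$design, extra)
  expect_warning(calls <- call_arm_switches(x$profiles, design),
                 "zero replicates")
  expect_equal(nrow(calls), 1L)
})

test_that("compare modes restrict which condition pairs are examined", {
  x <- make_profiles(list("C08:root:4h" = c(0.9, 0.9),
                          "W05:leaf:4h" = c(0.1, 0.1)))
  # different accession AND different tissue: not a default pair
  expect_equal(nrow(call_arm_switches(x$profiles, x$design)), 0L)
  expect_equal(nrow(call_arm_switches(x$profiles, x$design, compare = "all")), 1L)
  # same tissue/time across accessions is a default pair
  y <- make_profiles(list("C08:root:4h" = c(0.9, 0.9),
                          "W05:root:4h" = c(0.1, 0.1)))
  expect_equal(nrow(call_arm_switches(y$profiles, y$design)), 1L)
})
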