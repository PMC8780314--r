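# Readers/writers for every on-disk artifact: FASTA/FASTQ via Biostrings,
# GFF3 arm annotations, sample sheets, count matrices, INI-style config.
# All readers reject malformed records with the offending line number;
# internal coordinates are 0-based half-open (GFF3 on disk is 1-based
# inclusive); sequences are normalized to uppercase RNA.

#' Read a FASTA file as a named character vector of RNA sequences
#'
#' @param path FASTA file.
#' @return named character vector (ids from the first whitespace-delimited
#'   token of each header), sequences uppercase RNA.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  setNames(normalize_rna(as.character(ss)), ids)
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector (RNA or DNA).
#' @param path output file.
#' @param as_dna write U as T (default FALSE).
#' @export
write_fasta <- function(seqs, path, as_dna = FALSE) {
  x <- normalize_rna(seqs)
  if (as_dna) x <- chartr("U", "T", x)
  ss <- Biostrings::BStringSet(x)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file (Phred+33 qualities).
#' @return data.frame with columns `id`, `seq` (uppercase RNA) and `qual`
#'   (Phred+33 string), one row per read.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    id = sub("\\s.*$", "", names(ss)),
    seq = normalize_rna(as.character(ss)),
    qual = as.character(S4Vectors::mcols(ss)$qualities),
    stringsAsFactors = FALSE
  )
}

#' Write a read table to FASTQ (sequences emitted as DNA)
#'
#' @param reads data.frame with `id`, `seq`, `qual` columns.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual)))
    stop("sequence/quality length mismatch in reads to write")
  ss <- Biostrings::DNAStringSet(chartr("U", "T", normalize_rna(reads$seq)))
  names(ss) <- reads$id
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read hairpin arm annotations (FASTA + GFF3)
#'
#' Pairs each hairpin sequence with its annotated 5p and 3p arm intervals.
#' GFF3 rows of type `miRNA` must carry attributes `ID=`, `arm=5p|3p` and
#' `Derives_from=<hairpin_id>`; the seqid is the hairpin id. Coordinates are
#' converted from 1-based inclusive (on disk) to 0-based half-open.
#'
#' @param fasta hairpin FASTA path.
#' @param gff GFF3 path with arm rows.
#' @return list with `loci` (data.frame: hairpin_id, sequence, arm5p_start,
#'   arm5p_end, arm3p_start, arm3p_end, mature5p_id, mature3p_id; intervals
#'   0-based half-open) and `skipped` (data.frame: hairpin_id, reason).
#'   Malformed coordinates or out-of-bounds arms are hard errors naming the
#'   GFF line; hairpins lacking one or both arm rows go on the skip list.
#' @export
read_hairpin_annotation <- function(fasta, gff) {
  seqs <- read_fasta(fasta)
  raw <- readLines(gff)
  keep <- !grepl("^#", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  if (!any(keep)) {
    return(list(
      loci = empty_hairpin_loci(),
      skipped = data.frame(hairpin_id = names(seqs),
                           reason = rep("no_arms", length(seqs)))
    ))
  }
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("GFF line ", lineno[which(nf != 9L)[1]], ": expected 9 tab-separated fields")
  g <- data.frame(
    seqid = vapply(fields, `[[`, "", 1L),
    type  = vapply(fields, `[[`, "", 3L),
    start = suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L))),
    end   = suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L))),
    attrs = vapply(fields, `[[`, "", 9L),
    line  = lineno,
    stringsAsFactors = FALSE
  )
  g <- g[g$type == "miRNA", , drop = FALSE]
  if (anyNA(g$start) || anyNA(g$end))
    stop("GFF line ", g$line[which(is.na(g$start) | is.na(g$end))[1]],
         ": non-numeric coordinate")
  bad <- which(g$end < g$start)
  if (length(bad))
    stop("GFF line ", g$line[bad[1]], ": end < start")
  g$arm <- gff_attr(g$attrs, "arm")
  g$id <- gff_attr(g$attrs, "ID")
  g$hairpin <- gff_attr(g$attrs, "Derives_from")
  g$hairpin[is.na(g$hairpin)] <- g$seqid[is.na(g$hairpin)]
  badarm <- which(is.na(g$arm) | !(g$arm %in% c("5p", "3p")))
  if (length(badarm))
    stop("GFF line ", g$line[badarm[1]], ": missing or invalid arm attribute")

  loci <- list()
  skipped <- list()
  for (hid in names(seqs)) {
    rows <- g[g$hairpin == hid, , drop = FALSE]
    if (nrow(rows) == 0L) {
      skipped[[hid]] <- "no_arms"
      next
    }
    r5 <- rows[rows$arm == "5p", , drop = FALSE]
    r3 <- rows[rows$arm == "3p", , drop = FALSE]
    if (nrow(r5) == 0L) { skipped[[hid]] <- "missing_5p"; next }
    if (nrow(r3) == 0L) { skipped[[hid]] <- "missing_3p"; next }
    r5 <- r5[1L, ]; r3 <- r3[1L, ]
    len <- nchar(seqs[[hid]])
    for (r in list(r5, r3)) {
      if (r$start < 1L || r$end > len)
        stop("GFF line ", r$line, ": arm interval outside hairpin '", hid,
             "' (length ", len, ")")
    }
    # 1-based inclusive -> 0-based half-open
    a5 <- c(r5$start - 1L, r5$end)
    a3 <- c(r3$start - 1L, r3$end)
    if (a5[2] > a3[1])
      stop("GFF line ", r3$line, ": 5p arm must end before 3p arm starts on '",
           hid, "'")
    if ((a5[2] - a5[1]) < 16L || (a5[2] - a5[1]) > 30L ||
        (a3[2] - a3[1]) < 16L || (a3[2] - a3[1]) > 30L) {
      skipped[[hid]] <- "arm_length"
      next
    }
    loci[[hid]] <- data.frame(
      hairpin_id = hid, sequence = unname(seqs[[hid]]),
      arm5p_start = a5[1], arm5p_end = a5[2],
      arm3p_start = a3[1], arm3p_end = a3[2],
      mature5p_id = if (is.na(r5$id)) paste0(hid, "-5p") else r5$id,
      mature3p_id = if (is.na(r3$id)) paste0(hid, "-3p") else r3$id,
      stringsAsFactors = FALSE
    )
  }
  list(
    loci = if (length(loci)) do.call(rbind, c(loci, make.row.names = FALSE))
           else empty_hairpin_loci(),
    skipped = if (length(skipped))
      data.frame(hairpin_id = names(skipped), reason = unlist(skipped),
                 row.names = NULL, stringsAsFactors = FALSE)
    else data.frame(hairpin_id = character(), reason = character())
  )
}

empty_hairpin_loci <- function() {
  data.frame(hairpin_id = character(), sequence = character(),
             arm5p_start = integer(), arm5p_end = integer(),
             arm3p_start = integer(), arm3p_end = integer(),
             mature5p_id = character(), mature3p_id = character(),
             stringsAsFactors = FALSE)
}

gff_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0("(?:^|;)\\s*", key, "=([^;]+)"), attrs))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, character(1))
}

#' Write hairpin loci to GFF3
#'
#' Inverse of the GFF half of [read_hairpin_annotation()]: emits one `miRNA`
#' row per arm, converting internal 0-based half-open intervals back to
#' 1-based inclusive coordinates.
#'
#' @param loci hairpin loci data.frame.
#' @param path output GFF3 file.
#' @export
write_arm_gff <- function(loci, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(loci))) {
    l <- loci[i, ]
    writeLines(c(
      paste(l$hairpin_id, "armflip", "miRNA", l$arm5p_start + 1L, l$arm5p_end,
            ".", "+", ".",
            paste0("ID=", l$mature5p_id, ";arm=5p;Derives_from=", l$hairpin_id),
            sep = "\t"),
      paste(l$hairpin_id, "armflip", "miRNA", l$arm3p_start + 1L, l$arm3p_end,
            ".", "+", ".",
            paste0("ID=", l$mature3p_id, ";arm=3p;Derives_from=", l$hairpin_id),
            sep = "\t")
    ), con)
  }
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' @param tsv path to a tab-separated sheet with header columns `sample_id`,
#'   `accession`, `tissue`, `time_h`, `replicate` and at least one of
#'   `fastq_path` / `counts_path`.
#' @param tissues allowed tissue values.
#' @return validated data.frame of sample records. Duplicate sample ids,
#'   duplicate (accession, tissue, time_h, replicate) tuples, unknown tissues
#'   and missing file paths are hard errors carrying the offending line.
#' @export
read_sample_sheet <- function(tsv, tissues = c("root", "leaf")) {
  sheet <- read.delim(tsv, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(sheet) == 0L) stop("no samples in sheet '", tsv, "'")
  req <- c("sample_id", "accession", "tissue", "time_h", "replicate")
  miss <- setdiff(req, names(sheet))
  if (length(miss)) stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  pathcols <- intersect(c("fastq_path", "counts_path"), names(sheet))
  if (!length(pathcols)) stop("sample sheet needs a fastq_path or counts_path column")
  validate_sample_sheet(sheet, tissues = tissues, pathcols = pathcols)
  sheet$time_h <- as.numeric(sheet$time_h)
  sheet$replicate <- as.integer(sheet$replicate)
  sheet
}

validate_sample_sheet <- function(sheet, tissues = c("root", "leaf"),
                                  pathcols = intersect(c("fastq_path", "counts_path"),
                                                       names(sheet))) {
  line <- function(i) i + 1L  # header occupies line 1
  dup <- which(duplicated(sheet$sample_id))
  if (length(dup))
    stop("line ", line(dup[1]), ": duplicate sample_id '", sheet$sample_id[dup[1]], "'")
  badt <- which(!(sheet$tissue %in% tissues))
  if (length(badt))
    stop("line ", line(badt[1]), ": unknown tissue '", sheet$tissue[badt[1]], "'")
  key <- paste(sheet$accession, sheet$tissue, sheet$time_h, sheet$replicate, sep = "\r")
  dupk <- which(duplicated(key))
  if (length(dupk))
    stop("line ", line(dupk[1]), ": duplicate (accession, tissue, time_h, replicate)")
  if (any(suppressWarnings(as.integer(sheet$replicate)) < 1L, na.rm = TRUE) ||
      anyNA(suppressWarnings(as.integer(sheet$replicate))))
    stop("replicate must be a positive integer")
  if (length(pathcols)) {
    haspath <- Reduce(`|`, lapply(pathcols, function(cn) {
      !is.na(sheet[[cn]]) & nzchar(sheet[[cn]])
    }))
    if (any(!haspath))
      stop("line ", line(which(!haspath)[1]), ": missing file path")
  }
  invisible(TRUE)
}

#' Write a sample sheet
#' @param sheet sample records data.frame.
#' @param path output TSV.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a count matrix container
#'
#' @param counts non-negative integer matrix, features x samples, with
#'   dimnames.
#' @param library_sizes positive integer vector named by sample; the total
#'   reads retained after QC per sample (not the column sums: multi-assigned
#'   and unassigned reads would otherwise distort CPM).
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, library_sizes) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) > 0)
    stop("counts must have feature rownames")
  if (is.null(colnames(counts))) stop("counts must have sample colnames")
  if (any(counts < 0)) stop("negative counts")
  library_sizes <- library_sizes[colnames(counts)]
  if (anyNA(library_sizes) || any(library_sizes <= 0))
    stop("library_sizes must be positive and cover every sample")
  structure(list(counts = counts, library_sizes = library_sizes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts), "samples\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Write a count matrix to TSV
#'
#' Library sizes are stored in a `#library_sizes:` header comment so the
#' round trip is exact.
#'
#' @param m `count_matrix`.
#' @param path output TSV.
#' @export
write_count_matrix <- function(m, path) {
  stopifnot(inherits(m, "count_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#library_sizes: ",
                    paste(colnames(m$counts), m$library_sizes,
                          sep = "=", collapse = ";")), con)
  writeLines(paste(c("feature_id", colnames(m$counts)), collapse = "\t"), con)
  if (nrow(m$counts) > 0) {
    rows <- apply(m$counts, 1L, function(v) paste(v, collapse = "\t"))
    writeLines(paste(rownames(m$counts), rows, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param path TSV path.
#' @return `count_matrix`. Negative entries are hard errors with line number.
#' @export
read_count_matrix <- function(path) {
  raw <- readLines(path)
  if (!length(raw) || !grepl("^#library_sizes:", raw[1]))
    stop("'", path, "' lacks a #library_sizes header")
  libspec <- strsplit(sub("^#library_sizes:\\s*", "", raw[1]), ";", fixed = TRUE)[[1]]
  kv <- strsplit(libspec, "=", fixed = TRUE)
  libs <- setNames(as.numeric(vapply(kv, `[[`, "", 2L)),
                   vapply(kv, `[[`, "", 1L))
  header <- strsplit(raw[2], "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  body <- raw[-(1:2)]
  body <- body[nzchar(body)]
  if (!length(body)) {
    counts <- matrix(integer(), nrow = 0, ncol = length(samples),
                     dimnames = list(NULL, samples))
    return(count_matrix(counts, libs))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != length(header)))
    stop("line ", which(lengths(parts) != length(header))[1] + 2L,
         ": wrong number of columns")
  vals <- suppressWarnings(
    vapply(parts, function(p) as.numeric(p[-1]), numeric(length(samples))))
  vals <- matrix(vals, ncol = length(samples), byrow = TRUE,
                 dimnames = list(vapply(parts, `[[`, "", 1L), samples))
  if (anyNA(vals))
    stop("line ", which(apply(is.na(vals), 1, any))[1] + 2L, ": non-numeric count")
  neg <- which(apply(vals < 0, 1, any))
  if (length(neg)) stop("line ", neg[1] + 2L, ": negative count")
  count_matrix(vals, libs)
}

#' Parse an INI-style plain-text config file
#'
#' `key = value` lines, optional `[section]` headers nesting keys one level,
#' `#` comments. Values that parse as numbers become numeric; `true`/`false`
#' become logical; comma-separated values become vectors.
#'
#' @param path config file.
#' @return nested named list.
#' @export
read_config <- function(path) {
  raw <- readLines(path)
  raw <- sub("#.*$", "", raw)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw)]
  out <- list()
  section <- NULL
  for (ln in raw) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    if (!grepl("=", ln, fixed = TRUE)) stop("config line not key = value: '", ln, "'")
    key <- trimws(sub("=.*$", "", ln))
    val <- config_value(trimws(sub("^[^=]*=", "", ln)))
    if (is.null(section)) out[[key]] <- val else out[[section]][[key]] <- val
  }
  out
}

config_value <- function(v) {
  if (grepl(",", v, fixed = TRUE)) {
    return(unlist(lapply(trimws(strsplit(v, ",", fixed = TRUE)[[1]]), config_value)))
  }
  if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  v
}

#' Write a nested list as an INI-style config file
#' @param cfg nested named list (one level of sections).
#' @param path output file.
#' @export
write_config <- function(cfg, path) {
  fmt <- function(v) paste(vapply(v, function(x) {
    if (is.logical(x)) tolower(as.character(x)) else as.character(x)
  }, character(1)), collapse = ", ")
  con <- file(path, "w")
  on.exit(close(con))
  scalars <- cfg[!vapply(cfg, is.list, logical(1))]
  for (k in names(scalars)) writeLines(paste(k, "=", fmt(scalars[[k]])), con)
  sections <- cfg[vapply(cfg, is.list, logical(1))]
  for (s in names(sections)) {
    writeLines(paste0("[", s, "]"), con)
    for (k in names(sections[[s]]))
      writeLines(paste(k, "=", fmt(sections[[s]][[k]])), con)
  }
  invisible(path)
}
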