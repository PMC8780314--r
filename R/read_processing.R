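# Adapter trimming and read QC applied before arm quantification: a read is
# kept iff its mean Phred quality is >= 20 and its trimmed length falls in
# the 16-30 nt small RNA window.

#' Read filter parameters
#'
#' @param min_phred minimum Phred quality (default 20); compared against the
#'   mean read quality by default, see `quality_mode` in [filter_reads()].
#' @param min_len,max_len retained length window in nt (defaults 16 and 30,
#'   the PAGE-selected small RNA size range).
#' @param adapter3p 3' adapter sequence; empty string disables trimming.
#' @return list of class `read_filter_params`.
#' @export
read_filter_params <- function(min_phred = 20L, min_len = 16L, max_len = 30L,
                               adapter3p = "") {
  stopifnot(min_len > 0L, min_len <= max_len, min_phred >= 0)
  structure(list(min_phred = min_phred, min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 adapter3p = if (nzchar(adapter3p)) normalize_rna(adapter3p) else ""),
            class = "read_filter_params")
}

#' Trim a 3' adapter from reads
#'
#' Truncates each read at the leftmost position where the read suffix
#' matches a prefix of the adapter with at least `min_overlap` bases and
#' zero mismatches; qualities are truncated in lockstep. Reads without an
#' adapter hit pass unchanged; an empty adapter is a no-op.
#'
#' @param reads data.frame with `seq` (RNA) and `qual` columns (see
#'   [read_fastq()]).
#' @param adapter3p adapter sequence (T/U interchangeable).
#' @param min_overlap minimum adapter prefix length to trigger trimming
#'   (default 5).
#' @return the read table with trimmed `seq`/`qual`.
#' @export
trim_adapter <- function(reads, adapter3p, min_overlap = 5L) {
  if (is.null(adapter3p) || !nzchar(adapter3p)) return(reads)
  adapter <- normalize_rna(adapter3p)
  alen <- nchar(adapter)
  cut <- vapply(reads$seq, function(s) {
    n <- nchar(s)
    for (p in seq_len(n)) {
      ov <- min(n - p + 1L, alen)
      if (ov < min_overlap) break
      if (substr(s, p, p + ov - 1L) == substr(adapter, 1L, ov)) return(p - 1L)
    }
    n
  }, integer(1), USE.NAMES = FALSE)
  reads$seq <- substr(reads$seq, 1L, cut)
  reads$qual <- substr(reads$qual, 1L, cut)
  reads
}

#' Quality and length filter for small RNA reads
#'
#' A read is kept iff its Phred quality (mean by default) is at least
#' `min_phred` AND its length lies in `[min_len, max_len]`. Reads failing
#' quality are tallied under "quality" (checked first); remaining failures
#' under "length". `kept + sum(tally) == nrow(reads)` always holds, and the
#' filter is idempotent.
#'
#' @param reads read table (`seq`, `qual`, Phred+33).
#' @param params [read_filter_params()].
#' @param quality_mode "mean" (default) or "min": summary of per-base
#'   qualities compared against `min_phred`.
#' @return list with `kept` (read table) and `tally` (named integer vector
#'   with entries `quality` and `length`).
#' @export
filter_reads <- function(reads, params = read_filter_params(),
                         quality_mode = c("mean", "min")) {
  quality_mode <- match.arg(quality_mode)
  if (any(nchar(reads$seq) != nchar(reads$qual)))
    stop("read ", which(nchar(reads$seq) != nchar(reads$qual))[1],
         ": quality string length differs from sequence length")
  len <- nchar(reads$seq)
  q <- vapply(reads$qual, function(s) {
    if (!nzchar(s)) return(Inf)  # empty read: rejected by length, not quality
    ph <- utf8ToInt(s) - 33L
    if (quality_mode == "mean") mean(ph) else min(ph)
  }, numeric(1), USE.NAMES = FALSE)
  bad_q <- q < params$min_phred
  bad_l <- !bad_q & (len < params$min_len | len > params$max_len)
  keep <- !bad_q & !bad_l
  list(
    kept = reads[keep, , drop = FALSE],
    tally = c(quality = sum(bad_q), length = sum(bad_l))
  )
}
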