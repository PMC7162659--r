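#' QC parameter set for raw PAR-CLIP reads
#'
#' @param min_length minimum read length after adapter trimming (nt).
#' @param max_low_q10 maximum tolerated bases with quality < 10.
#' @param max_low_q13 maximum tolerated bases with quality < 13.
#' @param adapter_3p,adapter_5p adapter sequences (3' adapter is searched
#'   and trimmed; the 5' adapter defines ligation-product reads).
#' @param quality_offset ASCII offset of the quality encoding (33 = Sanger).
#' @return a list of class `qc_params`.
#' @export
qc_params <- function(min_length = 18L, max_low_q10 = 4L, max_low_q13 = 6L,
                      adapter_3p = "TCGTATGCCGTCTTCTGCTTG",
                      adapter_5p = "GTTCAGAGTTCTACAGTCCGACGATC",
                      quality_offset = 33L) {
  stopifnot(min_length >= 1, max_low_q10 >= 0, max_low_q13 >= 0)
  structure(list(min_length = as.integer(min_length),
                 max_low_q10 = as.integer(max_low_q10),
                 max_low_q13 = as.integer(max_low_q13),
                 adapter_3p = adapter_3p, adapter_5p = adapter_5p,
                 quality_offset = as.integer(quality_offset)),
            class = "qc_params")
}

# internal: position of the 3' adapter in a read (first match of the
# adapter's first `k` bases), or NA when absent
.find_adapter <- function(seq, adapter, k = 8L) {
  probe <- substr(adapter, 1L, min(k, nchar(adapter)))
  p <- regexpr(probe, seq, fixed = TRUE)
  if (p < 0) NA_integer_ else as.integer(p)
}

#' Filter raw PAR-CLIP reads
#'
#' A read survives iff it fails none of the removal rules, evaluated in
#' this order (a read is charged to the first failing rule): trimmed
#' length below `min_length`; trimmed sequence is a homopolymer of A;
#' missing 3' adapter; 5'-3' or 5'-5' adapter ligation product (the
#' trimmed insert begins with the 5' adapter or its reverse complement);
#' more than `max_low_q10` bases with quality below 10; more than
#' `max_low_q13` bases with quality below 13.
#'
#' @param fastq path to a FASTQ file, or a `data.frame` with `seq` and
#'   `qual` character columns.
#' @param params a [qc_params()] object.
#' @return list with `reads` (surviving reads, trimmed), `removed`
#'   (named counts per rule) and `n_input`.
#' @export
filter_raw_reads <- function(fastq, params = qc_params()) {
  if (is.character(fastq)) {
    dss <- Biostrings::readDNAStringSet(fastq, format = "fastq",
                                        with.qualities = TRUE)
    recs <- data.frame(seq = as.character(dss),
                       qual = as.character(S4Vectors::mcols(dss)$qualities),
                       stringsAsFactors = FALSE)
  } else recs <- fastq
  rules <- c("min_length", "homopolymer_A", "no_3p_adapter",
             "adapter_ligation", "low_quality_q10", "low_quality_q13")
  removed <- stats::setNames(integer(length(rules)), rules)
  keep_seq <- character(0); keep_qual <- character(0)
  rc5 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(params$adapter_5p)))
  for (i in seq_len(nrow(recs))) {
    s <- recs$seq[i]; q <- recs$qual[i]
    if (is.na(s) || is.na(q) || nchar(s) != nchar(q) || nchar(s) == 0)
      .fail("malformed FASTQ record at index %d", i)
    apos <- .find_adapter(s, params$adapter_3p)
    trimmed <- if (is.na(apos)) s else substr(s, 1L, apos - 1L)
    tq <- if (is.na(apos)) q else substr(q, 1L, apos - 1L)
    fail <- NULL
    if (nchar(trimmed) < params$min_length) fail <- "min_length"
    else if (nchar(trimmed) > 0 &&
             trimmed == strrep("A", nchar(trimmed))) fail <- "homopolymer_A"
    else if (is.na(apos)) fail <- "no_3p_adapter"
    else if (startsWith(trimmed, substr(params$adapter_5p, 1L, 8L)) ||
             startsWith(trimmed, substr(rc5, 1L, 8L))) fail <- "adapter_ligation"
    else {
      qv <- utf8ToInt(tq) - params$quality_offset
      if (sum(qv < 10) > params$max_low_q10) fail <- "low_quality_q10"
      else if (sum(qv < 13) > params$max_low_q13) fail <- "low_quality_q13"
    }
    if (is.null(fail)) {
      keep_seq <- c(keep_seq, trimmed); keep_qual <- c(keep_qual, tq)
    } else removed[fail] <- removed[fail] + 1L
  }
  list(reads = data.frame(seq = keep_seq, qual = keep_qual,
                          stringsAsFactors = FALSE),
       removed = removed, n_input = nrow(recs))
}
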