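#' @name gbody_io
#' @title Readers and writers for the pipeline's file formats
#'
#' @description
#' Plain-text interchange formats: aligned reads as 8-column TSV, binding
#' sites as BED6+2 (extra columns `rpm`, `n_conversion_reads`), gene count
#' tables as gene x library TSV, qPCR Cq tables, FRAP traces and
#' competition observations as TSV, image stacks as multi-page TIFF with a
#' JSON sidecar carrying the pixel size, and JSON reports. Readers
#' validate schemas and name the file, line and field in errors; every
#' writer/reader pair round-trips losslessly.
NULL

.read_tsv <- function(path, required, what) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    .fail("%s: %s is missing column(s): %s", what, path,
          paste(missing, collapse = ", "))
  df
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname gbody_io
#' @param reads aligned-read table ([simulate_parclip_reads()] schema).
#' @param path file path.
#' @export
write_reads_tsv <- function(reads, path) {
  tm <- attr(reads, "total_mapped")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(tm)) writeLines(sprintf("# total_mapped=%d", tm), con)
  utils::write.table(reads, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname gbody_io
#' @export
read_reads_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  tm <- NULL
  if (startsWith(first, "# total_mapped="))
    tm <- as.integer(sub("# total_mapped=", "", first))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  req <- c("chrom", "start", "end", "name", "conversion_count", "strand",
           "read_length", "dataset")
  missing <- setdiff(req, names(df))
  if (length(missing))
    .fail("reads TSV %s is missing column(s): %s", path,
          paste(missing, collapse = ", "))
  bad <- which(df$end <= df$start | df$start < 0)
  if (length(bad))
    .fail("reads TSV %s: invalid interval at line %d (field start/end)",
          path, bad[1] + 1L + !is.null(tm))
  if (!is.null(tm)) attr(df, "total_mapped") <- tm
  df
}

#' @rdname gbody_io
#' @param sites binding-site table.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(chrom = sites$chrom, start = sites$start,
                    end = sites$end,
                    name = sprintf("site%05d", seq_len(nrow(sites))),
                    score = 0L, strand = sites$strand,
                    rpm = sites$rpm,
                    n_conversion_reads = sites$n_conversion_reads)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname gbody_io
#' @export
read_sites_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 8)
    .fail("BED6+2 %s: expected 8 columns, found %d", path, ncol(df))
  names(df) <- c("chrom", "start", "end", "name", "score", "strand",
                 "rpm", "n_conversion_reads")
  bad <- which(df$end <= df$start | df$start < 0 | df$rpm < 0)
  if (length(bad))
    .fail("BED6+2 %s: invalid record at line %d", path, bad[1])
  df[c("chrom", "start", "end", "strand", "rpm", "n_conversion_reads")]
}

#' @rdname gbody_io
#' @param tab gene table (`gene_id` + numeric library columns).
#' @export
write_gene_table <- function(tab, path) .write_tsv(tab, path)

#' @rdname gbody_io
#' @export
read_gene_table <- function(path) {
  df <- .read_tsv(path, "gene_id", "gene table")
  libs <- setdiff(names(df), "gene_id")
  for (lib in libs) {
    bad <- which(!is.finite(df[[lib]]) | df[[lib]] < 0)
    if (length(bad))
      .fail("gene table %s: negative or non-numeric value at line %d, field %s",
            path, bad[1] + 1L, lib)
  }
  df
}

#' @rdname gbody_io
#' @param cq Cq table (`probe_id`, `cq_eluate`, `cq_ft`, `fraction`).
#' @export
write_cq_table <- function(cq, path) .write_tsv(cq, path)

#' @rdname gbody_io
#' @export
read_cq_table <- function(path) {
  df <- .read_tsv(path, c("probe_id", "cq_eluate", "cq_ft", "fraction"),
                  "Cq table")
  bad <- which(!is.finite(df$cq_eluate) | !is.finite(df$cq_ft) |
                 df$fraction <= 0 | df$fraction > 1)
  if (length(bad)) .fail("Cq table %s: invalid record at line %d",
                         path, bad[1] + 1L)
  df
}

#' @rdname gbody_io
#' @param trace a FRAP trace list.
#' @export
write_trace_tsv <- function(trace, path) {
  df <- data.frame(time = trace$times, raw = trace$raw)
  for (k in seq_len(ncol(trace$controls)))
    df[[sprintf("control_%d", k)]] <- trace$controls[, k]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# background=%g bleach_index=%d",
                     trace$background, trace$bleach_index), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname gbody_io
#' @export
read_trace_tsv <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("# background=([-0-9.eE]+) bleach_index=([0-9]+)", hdr))[[1]]
  if (length(m) != 3) .fail("trace TSV %s: missing header line", path)
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  ctrl_cols <- grep("^control_", names(df), value = TRUE)
  if (!all(c("time", "raw") %in% names(df)) || !length(ctrl_cols))
    .fail("trace TSV %s: need time, raw and control_* columns", path)
  list(times = df$time, raw = df$raw,
       controls = as.matrix(df[ctrl_cols]),
       background = as.numeric(m[2]), bleach_index = as.integer(m[3]))
}

#' @rdname gbody_io
#' @param stack 3D numeric array.
#' @param pixel_size micrometers per pixel, stored in the JSON sidecar.
#' @export
write_image_stack <- function(stack, path, pixel_size = NA_real_) {
  lo <- min(stack)
  span <- max(max(stack) - lo, 1e-12)
  slices <- lapply(seq_len(dim(stack)[3]),
                   function(z) (stack[, , z] - lo) / span)
  tiff::writeTIFF(slices, path, bits.per.sample = 32L)
  meta <- list(pixel_size_um = pixel_size, scale = span, offset = lo,
               dim = dim(stack))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname gbody_io
#' @export
read_image_stack <- function(path) {
  slices <- tiff::readTIFF(path, all = TRUE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  scale <- if (!is.null(meta$scale)) meta$scale else 1
  offset <- if (!is.null(meta$offset)) meta$offset else 0
  stack <- array(0, c(dim(slices[[1]]), length(slices)))
  for (z in seq_along(slices))
    stack[, , z] <- slices[[z]] * scale + offset
  attr(stack, "pixel_size_um") <-
    if (!is.null(meta$pixel_size_um)) as.numeric(meta$pixel_size_um)
    else NA_real_
  stack
}

#' @rdname gbody_io
#' @param stack_attr an image stack read by [read_image_stack()].
#' @export
require_pixel_size <- function(stack_attr) {
  ps <- attr(stack_attr, "pixel_size_um")
  if (is.null(ps) || is.na(ps))
    .fail("pixel size required: the stack has no pixel-size metadata")
  ps
}

#' @rdname gbody_io
#' @param obs a `competition_obs`.
#' @export
write_competition_tsv <- function(obs, path) {
  df <- data.frame(pct_mix = obs$pct_mix, pct_gb_plus = obs$pct_gb_plus,
                   pct_gb_minus = obs$pct_gb_minus,
                   n_cells = obs$n_cells,
                   count_mix = obs$counts[["mix"]],
                   count_plus = obs$counts[["plus"]],
                   count_minus = obs$counts[["minus"]])
  .write_tsv(df, path)
}

#' @rdname gbody_io
#' @export
read_competition_tsv <- function(path) {
  df <- .read_tsv(path, c("pct_mix", "pct_gb_plus", "pct_gb_minus"),
                  "competition table")
  bad <- which(df$pct_mix < 0 | df$pct_mix > 100 |
                 df$pct_gb_plus < 0 | df$pct_gb_plus > 100 |
                 df$pct_gb_minus < 0 | df$pct_gb_minus > 100)
  if (length(bad)) .fail("competition table %s: percentage outside [0,100] at line %d",
                         path, bad[1] + 1L)
  obs <- list(pct_mix = df$pct_mix[1], pct_gb_plus = df$pct_gb_plus[1],
              pct_gb_minus = df$pct_gb_minus[1])
  if (all(c("n_cells", "count_mix", "count_plus", "count_minus") %in% names(df))) {
    obs$n_cells <- df$n_cells[1]
    obs$counts <- c(mix = df$count_mix[1], plus = df$count_plus[1],
                    minus = df$count_minus[1])
  }
  structure(obs, class = "competition_obs")
}

#' @rdname gbody_io
#' @param report named list.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
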