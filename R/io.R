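## Plain-text readers and writers.
##
## Windows as BED4+ (chrom, start, end, n_sim, partial), counts and panels
## as TSV, calls as BED6+ and VCF 4.2 (symbolic <DEL>/<DUP> with END/SVLEN
## and a CN FORMAT field). Every file opens with comment lines recording
## the tool version and the metadata needed to rebuild the in-memory
## object, so writing then reading reproduces it. Coordinates are 0-based
## half-open in BED/TSV and 1-based in VCF, per the formats' conventions.

pscc_version <- function() as.character(utils::packageVersion("pscc"))

meta_lines <- function(kv) {
  c(sprintf("## pscc=%s", pscc_version()),
    sprintf("## %s=%s", names(kv), vapply(kv, as.character, "")))
}

read_meta <- function(path) {
  ln <- readLines(path)
  hdr <- grep("^##", ln, value = TRUE)
  kv <- sub("^## ?", "", hdr)
  kv <- kv[grepl("=", kv)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(as.list(vals), keys)
}

write_body <- function(df, path, kv, col_header = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_lines(kv), con)
  if (col_header) writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

read_body <- function(path, col_classes = NA) {
  ln <- readLines(path)
  body_at <- which(!grepl("^##", ln))
  hdr <- ln[body_at[1L]]
  if (!startsWith(hdr, "#")) stop("missing column header line in ", path)
  cols <- strsplit(sub("^#", "", hdr), "\t")[[1L]]
  body <- ln[body_at[-1L]]
  if (!length(body)) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                        cols), stringsAsFactors = FALSE)
    return(df)
  }
  df <- utils::read.table(text = body, sep = "\t", header = FALSE,
                          col.names = cols, colClasses = col_classes,
                          stringsAsFactors = FALSE, quote = "")
  df
}

#' Write / read observation windows (BED4+)
#'
#' @param windows A `"pscc_windows"` table.
#' @param path Output/input file path.
#' @return `read_windows_bed()` returns the `"pscc_windows"` object.
#' @export
write_windows_bed <- function(windows, path) {
  stopifnot(inherits(windows, "pscc_windows"))
  kv <- list(expected_rc = attr(windows, "expected_rc"),
             n_w = attr(windows, "n_w"),
             read_length = attr(windows, "read_length"),
             U_sim = attr(windows, "U_sim"))
  kv <- kv[!vapply(kv, is.null, TRUE)]
  write_body(windows[, c("chrom", "start", "end", "n_sim", "partial")],
             path, kv)
  invisible(path)
}

#' @rdname write_windows_bed
#' @export
read_windows_bed <- function(path) {
  meta <- read_meta(path)
  df <- read_body(path)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$n_sim <- suppressWarnings(as.integer(df$n_sim))
  df$partial <- as.logical(df$partial)
  df$window <- seq_len(nrow(df))
  df <- df[, c("window", "chrom", "start", "end", "n_sim", "partial")]
  for (k in c("expected_rc", "n_w", "read_length", "U_sim"))
    if (!is.null(meta[[k]])) attr(df, k) <- as.numeric(meta[[k]])
  class(df) <- c("pscc_windows", "data.frame")
  df
}

#' Write / read a per-window count track (TSV)
#'
#' @param track A `"pscc_counts"` track.
#' @param path Output/input file path.
#' @return `read_counts_tsv()` returns the `"pscc_counts"` track.
#' @export
write_counts_tsv <- function(track, path) {
  kv <- list(sample_id = attr(track, "sample_id") %||% "sample",
             gc_corrected = isTRUE(attr(track, "gc_corrected")))
  write_body(track[, c("window", "chrom", "start", "end", "count", "gc",
                       "usable")], path, kv)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  meta <- read_meta(path)
  df <- read_body(path)
  for (k in c("window", "start", "end")) df[[k]] <- as.integer(df[[k]])
  df$count <- as.numeric(df$count)
  df$gc <- suppressWarnings(as.numeric(df$gc))
  df$usable <- as.logical(df$usable)
  attr(df, "sample_id") <- meta$sample_id
  if (isTRUE(as.logical(meta$gc_corrected))) attr(df, "gc_corrected") <- TRUE
  class(df) <- c("pscc_counts", "data.frame")
  df
}

#' Write / read a control panel (TSV)
#'
#' @param panel A `"pscc_panel"`.
#' @param path Output/input file path.
#' @return `read_panel_tsv()` returns the `"pscc_panel"`.
#' @export
write_panel_tsv <- function(panel, path) {
  stopifnot(inherits(panel, "pscc_panel"))
  kv <- list(n_controls = attr(panel, "n_controls"),
             target_median = attr(panel, "target_median"))
  write_body(panel[, c("window", "chrom", "start", "end", "mu", "sigma",
                       "usable")], path, kv)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path) {
  meta <- read_meta(path)
  df <- read_body(path)
  for (k in c("window", "start", "end")) df[[k]] <- as.integer(df[[k]])
  df$mu <- as.numeric(df$mu); df$sigma <- as.numeric(df$sigma)
  df$usable <- as.logical(df$usable)
  attr(df, "n_controls") <- as.integer(meta$n_controls)
  attr(df, "target_median") <- as.numeric(meta$target_median)
  class(df) <- c("pscc_panel", "data.frame")
  df
}

#' Write / read CNV calls (BED6+)
#'
#' BED6 columns chrom, start, end, name (state), score (0), strand (`.`),
#' plus copy_number, mean_rcr, n_windows, st_p, pt_p, sample.
#'
#' @param calls A calls table from [call_cnvs()].
#' @param path Output/input file path.
#' @return `read_calls_bed()` returns the calls `data.frame`.
#' @export
write_calls_bed <- function(calls, path) {
  n <- nrow(calls)
  df <- data.frame(chrom = calls$chrom, start = calls$start,
                   end = calls$end, name = calls$state,
                   score = rep(0L, n), strand = rep(".", n),
                   copy_number = calls$copy_number,
                   mean_rcr = calls$mean_rcr, n_windows = calls$n_windows,
                   st_p = calls$st_p, pt_p = calls$pt_p,
                   sample = calls$sample, stringsAsFactors = FALSE)
  write_body(df, path, list(n_calls = nrow(df)))
  invisible(path)
}

#' @rdname write_calls_bed
#' @export
read_calls_bed <- function(path) {
  df <- read_body(path)
  if (!nrow(df)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), state = character(0),
                      copy_number = integer(0), mean_rcr = numeric(0),
                      n_windows = integer(0), st_p = numeric(0),
                      pt_p = numeric(0), sample = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(chrom = df$chrom, start = as.integer(df$start),
                    end = as.integer(df$end), state = df$name,
                    copy_number = as.integer(df$copy_number),
                    mean_rcr = as.numeric(df$mean_rcr),
                    n_windows = as.integer(df$n_windows),
                    st_p = as.numeric(df$st_p), pt_p = as.numeric(df$pt_p),
                    sample = df$sample, stringsAsFactors = FALSE)
  out
}

#' Write CNV calls as VCF 4.2
#'
#' Emits symbolic `<DEL>` / `<DUP>` records with `END`, `SVLEN` and
#' `SVTYPE` INFO fields and a `CN` (copy number) FORMAT field for the
#' sample. Positions are 1-based per the VCF convention.
#'
#' @param calls A calls table from [call_cnvs()].
#' @param path Output file path.
#' @param sample_id Sample column name; defaults to the calls' sample.
#' @param contigs Optional named vector of contig lengths for the header.
#' @export
write_calls_vcf <- function(calls, path,
                            sample_id = unique(calls$sample)[1] %||% "sample",
                            contigs = NULL) {
  if (is.na(sample_id)) sample_id <- "sample"
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=pscc-%s", pscc_version()),
           "##ALT=<ID=DEL,Description=\"Deletion\">",
           "##ALT=<ID=DUP,Description=\"Duplication\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Difference in length between REF and ALT alleles\">",
           "##FORMAT=<ID=CN,Number=1,Type=Integer,Description=\"Copy number\">")
  if (!is.null(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_id, sep = "\t"))
  rows <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    del <- calls$state[i] == "deletion"
    svlen <- (calls$end[i] - calls$start[i]) * if (del) -1L else 1L
    rows[i] <- paste(calls$chrom[i], calls$start[i] + 1L,
                     sprintf("cnv%d", i), "N",
                     if (del) "<DEL>" else "<DUP>", ".", "PASS",
                     sprintf("END=%d;SVTYPE=%s;SVLEN=%d", calls$end[i],
                             if (del) "DEL" else "DUP", svlen),
                     "CN", calls$copy_number[i], sep = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}
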