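# Readers and writers: FASTA, BED (0-based half-open), GFF3 (converted on
# read), and the package's TSV table formats. TSVs are tab-delimited with a
# mandatory header row and "." for missing values.

#' Read a (multi-record) FASTA file
#'
#' @param path FASTA file.
#' @return named \code{DNAStringSet}, sequences upper-cased, record order
#'   preserved; names are the first whitespace-delimited token of each
#'   header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop("malformed FASTA in ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  if (length(x) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  out <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(out) <- vapply(strsplit(names(x), "\\s+"), `[[`, character(1), 1L)
  out
}

#' Write sequences to FASTA
#'
#' @param x named \code{DNAStringSet} or character vector.
#' @param path output file.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a BED file as 0-based half-open intervals
#'
#' @param path BED file (3-6 columns).
#' @return data.frame: chrom, start, end (0-based half-open), and name,
#'   score, strand when present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  md <- as.data.frame(S4Vectors::mcols(gr))
  if ("name" %in% names(md)) df$name <- as.character(md$name)
  if ("score" %in% names(md)) df$score <- md$score
  df$strand <- as.character(GenomicRanges::strand(gr))
  if (any(df$end <= df$start)) {
    stop("invalid BED interval (end <= start) in ", path, call. = FALSE)
  }
  df
}

#' Write intervals to BED (0-based half-open)
#'
#' @param x data.frame with chrom, start, end and optional name, score,
#'   strand columns.
#' @param path output file.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (any(x$end <= x$start)) stop("invalid interval (end <= start)", call. = FALSE)
  bed <- data.frame(x$chrom, x$start, x$end,
                    if ("name" %in% names(x)) x$name else ".",
                    if ("score" %in% names(x)) x$score else 0L,
                    if ("strand" %in% names(x)) x$strand else "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write probes as BED
#'
#' Six-column BED: chrom, start, end, probe_id, score = round(Tm x 10),
#' strand "+".
#'
#' @param probes probe data.frame.
#' @param path output file.
#' @export
write_probe_bed <- function(probes, path) {
  write_bed(data.frame(chrom = probes$chrom, start = probes$start,
                       end = probes$end, name = probes$probe_id,
                       score = as.integer(round(probes$tm * 10)),
                       strand = "+", stringsAsFactors = FALSE),
            path)
}

#' Read gene-model features from GFF3 or BED
#'
#' GFF3 is 1-based closed on disk and is converted to the package's 0-based
#' half-open convention (start - 1); BED is already 0-based.
#'
#' @param path feature file (.gff/.gff3 or .bed).
#' @param types optional GFF3 types to keep (e.g. "gene").
#' @return data.frame: feature_id, chrom, start, end.
#' @export
read_features <- function(path, types = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    if (!is.null(types)) gr <- gr[gr$type %in% types]
    md <- as.data.frame(S4Vectors::mcols(gr))
    id <- if ("ID" %in% names(md) && !all(is.na(md$ID))) as.character(md$ID)
          else sprintf("feature%d", seq_along(gr))
    data.frame(feature_id = id,
               chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  } else {
    df <- read_bed(path)
    data.frame(feature_id = if ("name" %in% names(df)) df$name
               else sprintf("feature%d", seq_len(nrow(df))),
               chrom = df$chrom, start = df$start, end = df$end,
               stringsAsFactors = FALSE)
  }
}

.write_tsv <- function(x, path) {
  df <- as.data.frame(x)
  for (j in seq_along(df)) df[[j]][is.na(df[[j]])] <- "."
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a ratio profile to TSV
#'
#' Columns: probe_id, chrom, start, end, stagger, log2_ratio; tab-delimited
#' with header, "." for missing.
#'
#' @param profile ratio profile data.frame.
#' @param path output file.
#' @export
write_ratio_tsv <- function(profile, path) {
  cols <- c("probe_id", "chrom", "start", "end", "stagger", "log2_ratio")
  if (!"stagger" %in% names(profile)) profile$stagger <- NA_integer_
  if (!"probe_id" %in% names(profile)) {
    profile$probe_id <- sprintf("p%d", seq_len(nrow(profile)))
  }
  df <- as.data.frame(profile)[, c(cols, intersect("set_id", names(profile)))]
  .write_tsv(df, path)
}

#' Read a ratio profile TSV
#'
#' @param path TSV as written by \code{\link{write_ratio_tsv}}.
#' @return ratio profile data.frame.
#' @export
read_ratio_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, na.strings = ".", stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "start", "end", "log2_ratio")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("ratio TSV ", path, " is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(df$end <= df$start)) stop("invalid probe interval in ", path, call. = FALSE)
  class(df) <- c("ratio_profile", "data.frame")
  df
}

#' Write a flat key-value metadata file
#'
#' @param config named list of scalar values (vectors are comma-joined).
#' @param path output file.
#' @export
write_metadata <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste0(k, "=", paste(format(v, trim = TRUE), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
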