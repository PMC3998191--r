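# Isothermal staggered probe design over a reference sequence.
#
# Coordinates are 0-based, half-open throughout the package; 1-based closed
# appears only in human-readable reports.

#' Probe design configuration
#'
#' Parameters controlling isothermal probe selection. Probe lengths are varied
#' within \code{[min_len, max_len]} so that every probe's melting temperature
#' is as close as possible to \code{target_tm} ("isothermal" design); ties are
#' broken toward the shorter length for determinism.
#'
#' @param min_len,max_len allowed probe lengths in bases (defaults 50 and 75).
#' @param target_tm target melting temperature in degrees Celsius (default 76,
#'   a typical isothermal long-oligo array target).
#' @param staggers base offsets between consecutive probe starts; the default
#'   is the nineteen-set ultra-high-density series 2..49 bp.
#' @param flank bases of flanking sequence to include on each side when
#'   designing over an annotated feature (default 500).
#' @param uniqueness_required drop probes whose sequence maps to more than one
#'   genomic location (default TRUE).
#' @param tm_method melting-temperature formula, \code{"nn"} or \code{"gc"}
#'   (see \code{\link{compute_tm}}).
#' @return a list of class \code{"design_config"}.
#' @export
design_config <- function(min_len = 50L, max_len = 75L, target_tm = 76,
                          staggers = c(2L, 6L, 10L, 12L, 15L, 17L, 20L, 22L,
                                       25L, 27L, 30L, 32L, 35L, 37L, 40L, 42L,
                                       45L, 47L, 49L),
                          flank = 500L, uniqueness_required = TRUE,
                          tm_method = c("nn", "gc")) {
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  stopifnot(1L <= min_len, min_len <= max_len, all(staggers >= 1L), flank >= 0L)
  structure(list(min_len = min_len, max_len = max_len, target_tm = target_tm,
                 staggers = as.integer(staggers), flank = as.integer(flank),
                 uniqueness_required = isTRUE(uniqueness_required),
                 tm_method = match.arg(tm_method)),
            class = "design_config")
}

.as_reference <- function(ref) {
  if (is.character(ref)) ref <- Biostrings::DNAStringSet(toupper(ref))
  if (!methods::is(ref, "DNAStringSet")) {
    stop("reference must be a DNAStringSet or named character vector", call. = FALSE)
  }
  if (length(ref) == 0L || any(Biostrings::width(ref) < 1L)) {
    stop("reference must contain at least one non-empty sequence", call. = FALSE)
  }
  if (is.null(names(ref))) names(ref) <- paste0("seq", seq_along(ref))
  ref
}

.empty_probes <- function() {
  data.frame(probe_id = character(), chrom = character(), start = integer(),
             end = integer(), length = integer(), sequence = character(),
             tm = numeric(), stagger = integer(), set_id = character(),
             stringsAsFactors = FALSE)
}

#' Design one isothermal probe at a fixed start
#'
#' Chooses, among all probe lengths in \code{[min_len, max_len]} that fit in
#' the reference, the length whose melting temperature is closest to
#' \code{cfg$target_tm}; ties go to the shorter probe. Windows containing an
#' ambiguous base (N) are rejected rather than redesigned: the function
#' returns \code{NULL} with attribute \code{reason = "contains_N"}.
#'
#' @param ref reference sequences (\code{DNAStringSet} or named character).
#' @param chrom name of the reference sequence to design on.
#' @param start 0-based probe start.
#' @param cfg a \code{\link{design_config}}.
#' @param max_end optional 0-based exclusive bound the probe must not cross
#'   (used to keep probes inside a region).
#' @return a one-row probe data.frame (probe_id, chrom, start, end, length,
#'   sequence, tm, stagger, set_id); a rejected window yields a zero-row
#'   frame carrying attribute \code{reason}.
#' @export
design_isothermal_probe <- function(ref, chrom, start, cfg = design_config(),
                                    max_end = NULL) {
  ref <- .as_reference(ref)
  if (!chrom %in% names(ref)) stop("unknown sequence: ", chrom, call. = FALSE)
  chrom_len <- length(ref[[chrom]])
  start <- as.integer(start)
  lim <- min(chrom_len, if (is.null(max_end)) chrom_len else as.integer(max_end))
  if (start < 0L || start + cfg$min_len > lim) {
    stop("probe window [", start, ", ", start + cfg$min_len,
         ") does not fit in ", chrom, call. = FALSE)
  }
  max_len <- min(cfg$max_len, lim - start)
  window <- as.character(Biostrings::subseq(ref[[chrom]], start + 1L,
                                            start + max_len))
  chars <- strsplit(window, "", fixed = TRUE)[[1L]]
  n_pos <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(n_pos) && n_pos[1L] <= cfg$min_len) {
    return(structure(.empty_probes(), reason = "contains_N"))
  }
  if (length(n_pos)) max_len <- n_pos[1L] - 1L
  tms <- .tm_prefixes(chars[seq_len(max_len)], cfg$min_len, max_len,
                      method = cfg$tm_method)
  best <- which.min(abs(tms - cfg$target_tm)) # first index = shortest on ties
  len <- cfg$min_len + best - 1L
  data.frame(probe_id = sprintf("%s_%d_%d", chrom, start, len),
             chrom = chrom, start = start, end = start + len, length = len,
             sequence = substr(window, 1L, len), tm = tms[best],
             stagger = NA_integer_, set_id = NA_character_,
             stringsAsFactors = FALSE)
}

#' Generate a staggered probe set over a region
#'
#' Places probe starts at \code{region_start, region_start + s, ...} for
#' stagger \code{s}, keeping every start from which at least a minimum-length
#' probe fits inside the region, and designs each probe isothermally with
#' \code{\link{design_isothermal_probe}}. Probes never extend past
#' \code{region_end}. Starts rejected (N-containing windows) are recorded in
#' the \code{removed} table.
#'
#' @param ref reference sequences.
#' @param chrom sequence name; \code{region_start,region_end} 0-based
#'   half-open region bounds.
#' @param stagger distance in bases between consecutive probe starts.
#' @param cfg a \code{\link{design_config}}.
#' @param set_id identifier stamped on the probes (default derived from the
#'   region and stagger).
#' @return an object of class \code{"staggered_probe_set"}: a list with
#'   \code{set_id}, \code{chrom}, \code{start}, \code{end}, \code{stagger},
#'   \code{probes} (data.frame) and \code{removed} (data.frame of start,
#'   reason).
#' @export
generate_staggered_set <- function(ref, chrom, region_start, region_end,
                                   stagger, cfg = design_config(),
                                   set_id = NULL) {
  ref <- .as_reference(ref)
  stagger <- as.integer(stagger)
  region_start <- as.integer(region_start); region_end <- as.integer(region_end)
  stopifnot(stagger >= 1L, region_start >= 0L)
  if (!chrom %in% names(ref)) stop("unknown sequence: ", chrom, call. = FALSE)
  if (region_end > length(ref[[chrom]])) {
    stop("region extends past end of ", chrom, call. = FALSE)
  }
  if (is.null(set_id)) {
    set_id <- sprintf("%s_%d_%d_s%d", chrom, region_start, region_end, stagger)
  }
  removed <- data.frame(start = integer(), reason = character(),
                        stringsAsFactors = FALSE)
  if (region_end - region_start < cfg$min_len) {
    warning("region shorter than min_len; empty probe set", call. = FALSE)
    probes <- .empty_probes()
  } else {
    starts <- seq.int(region_start, region_end - cfg$min_len, by = stagger)
    rows <- vector("list", length(starts))
    for (i in seq_along(starts)) {
      p <- design_isothermal_probe(ref, chrom, starts[i], cfg,
                                   max_end = region_end)
      if (nrow(p) == 0L) {
        removed <- rbind(removed, data.frame(start = starts[i],
                                             reason = attr(p, "reason"),
                                             stringsAsFactors = FALSE))
      } else {
        rows[[i]] <- p
      }
    }
    probes <- do.call(rbind, rows)
    if (is.null(probes)) probes <- .empty_probes()
  }
  if (nrow(probes)) {
    probes$stagger <- stagger
    probes$set_id <- set_id
    probes$probe_id <- sprintf("%s_%d", set_id, probes$start)
    rownames(probes) <- NULL
  }
  structure(list(set_id = set_id, chrom = chrom, start = region_start,
                 end = region_end, stagger = stagger, probes = probes,
                 removed = removed),
            class = "staggered_probe_set")
}

#' @export
print.staggered_probe_set <- function(x, ...) {
  cat(sprintf("staggered_probe_set %s: %s:%d-%d, stagger %d bp, %d probes (%d removed)\n",
              x$set_id, x$chrom, x$start, x$end, x$stagger,
              nrow(x$probes), nrow(x$removed)))
  invisible(x)
}

#' Filter probes that map to more than one genomic location
#'
#' A probe is kept if and only if its sequence, counting both strands
#' (i.e. the sequence or its reverse complement), occurs exactly once in the
#' full reference. Removals are logged with the hit count. The operation is
#' idempotent.
#'
#' @param probes probe data.frame (as produced by the design functions) or a
#'   \code{staggered_probe_set}.
#' @param ref reference sequences.
#' @return list with elements \code{kept} and \code{removed} (the latter with
#'   a \code{reason} and \code{n_hits} column).
#' @export
uniqueness_filter <- function(probes, ref) {
  if (inherits(probes, "staggered_probe_set")) probes <- probes$probes
  ref <- .as_reference(ref)
  if (!nrow(probes)) {
    return(list(kept = probes, removed = cbind(probes[0, ],
                reason = character(), n_hits = integer())))
  }
  uniq <- unique(probes$sequence)
  hits <- vapply(uniq, function(s) .genome_hit_count(s, ref), integer(1))
  n_hits <- hits[match(probes$sequence, uniq)]
  keep <- n_hits == 1L
  removed <- probes[!keep, , drop = FALSE]
  if (nrow(removed)) {
    removed$reason <- ifelse(n_hits[!keep] == 0L, "not_in_reference",
                             "multi_mapping")
    removed$n_hits <- as.integer(n_hits[!keep])
  } else {
    removed$reason <- character(0)
    removed$n_hits <- integer(0)
  }
  list(kept = probes[keep, , drop = FALSE], removed = removed)
}

# occurrences of `sequence` in the reference, both strands; a palindromic
# sequence is counted once per genomic location
.genome_hit_count <- function(sequence, ref) {
  pat <- Biostrings::DNAString(sequence)
  rc <- Biostrings::reverseComplement(pat)
  fwd <- sum(vapply(seq_along(ref), function(i) {
    Biostrings::countPattern(pat, ref[[i]])
  }, integer(1)))
  if (as.character(rc) == as.character(pat)) return(fwd)
  rev <- sum(vapply(seq_along(ref), function(i) {
    Biostrings::countPattern(rc, ref[[i]])
  }, integer(1)))
  fwd + rev
}

#' Design the full multi-stagger probe panel over a region
#'
#' Runs \code{\link{generate_staggered_set}} for every stagger in the
#' configuration and, when \code{cfg$uniqueness_required}, applies
#' \code{\link{uniqueness_filter}} against the whole reference. Returns the
#' sets plus a design manifest (one row per set: set_id, stagger, n_designed,
#' n_removed).
#'
#' @inheritParams generate_staggered_set
#' @param staggers staggers to design (default \code{cfg$staggers}).
#' @return list with \code{sets} (list of \code{staggered_probe_set}),
#'   \code{probes} (pooled kept probes) and \code{manifest} (data.frame).
#' @export
design_probe_sets <- function(ref, chrom, region_start, region_end,
                              cfg = design_config(), staggers = cfg$staggers) {
  ref <- .as_reference(ref)
  sets <- lapply(staggers, function(s) {
    set <- generate_staggered_set(ref, chrom, region_start, region_end, s, cfg)
    if (cfg$uniqueness_required && nrow(set$probes)) {
      flt <- uniqueness_filter(set$probes, ref)
      if (nrow(flt$removed)) {
        set$removed <- rbind(set$removed,
                             data.frame(start = flt$removed$start,
                                        reason = flt$removed$reason,
                                        stringsAsFactors = FALSE))
      }
      set$probes <- flt$kept
    }
    set
  })
  names(sets) <- vapply(sets, `[[`, character(1), "set_id")
  manifest <- data.frame(
    set_id = names(sets),
    stagger = unname(vapply(sets, `[[`, integer(1), "stagger")),
    n_designed = unname(vapply(sets, function(s) nrow(s$probes), integer(1))),
    n_removed = unname(vapply(sets, function(s) nrow(s$removed), integer(1))),
    row.names = NULL, stringsAsFactors = FALSE)
  pooled <- do.call(rbind, c(lapply(sets, `[[`, "probes"),
                             list(make.row.names = FALSE)))
  list(sets = sets, probes = pooled, manifest = manifest)
}
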