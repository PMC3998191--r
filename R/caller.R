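# Deletion/duplication calling from normalized log2-ratio profiles.

#' Caller configuration
#'
#' @param sd_multiplier threshold multiplier on the robust SD (default 2, the
#'   classic 2-SD deletion-profile threshold).
#' @param fixed_threshold optional absolute log2 threshold; when given it
#'   overrides the SD-derived value (e.g. pin to 0.4).
#' @param k_consecutive minimum run of consecutive flagged probes to call a
#'   segment (default 3; 2 is the relaxed setting).
#' @param feature_fraction fraction of a feature's probes that must fall at
#'   or below \code{feature_threshold} to call the feature deleted
#'   (default 0.5).
#' @param feature_threshold log2 cutoff for the feature-fraction rule
#'   (default -0.8).
#' @param max_gap non-flagged probes tolerated inside one segment
#'   (default 0: strictly consecutive).
#' @return list of class \code{"caller_config"}.
#' @export
caller_config <- function(sd_multiplier = 2, fixed_threshold = NULL,
                          k_consecutive = 3L, feature_fraction = 0.5,
                          feature_threshold = -0.8, max_gap = 0L) {
  k_consecutive <- as.integer(k_consecutive)
  stopifnot(k_consecutive >= 1L, feature_fraction > 0, feature_fraction <= 1,
            max_gap >= 0L)
  structure(list(sd_multiplier = sd_multiplier,
                 fixed_threshold = fixed_threshold,
                 k_consecutive = k_consecutive,
                 feature_fraction = feature_fraction,
                 feature_threshold = feature_threshold,
                 max_gap = as.integer(max_gap)),
            class = "caller_config")
}

#' Normalize a ratio profile
#'
#' Centres the log2 ratios so their median is exactly zero and attaches a
#' robust noise estimate (scaled median absolute deviation) as attribute
#' \code{sd_estimate}. Idempotent. When all values are identical the SD
#' estimate is zero and is flagged (attribute \code{sd_zero}); segment
#' calling then requires a fixed threshold.
#'
#' @param profile a \code{ratio_profile} data.frame (needs a
#'   \code{log2_ratio} column and at least two probes).
#' @return the profile with centred ratios and noise attributes.
#' @export
normalize_profile <- function(profile) {
  stopifnot("log2_ratio" %in% names(profile))
  if (nrow(profile) < 2L) stop("need at least 2 probes to normalize", call. = FALSE)
  med <- stats::median(profile$log2_ratio)
  profile$log2_ratio <- profile$log2_ratio - med
  sd_est <- stats::mad(profile$log2_ratio) # scaled MAD, consistent for Normal
  attr(profile, "sd_estimate") <- sd_est
  attr(profile, "sd_zero") <- sd_est == 0
  if (sd_est == 0) {
    warning("robust SD estimate is zero; supply a fixed_threshold for calling",
            call. = FALSE)
  }
  profile
}

#' Derive the deletion-profile threshold
#'
#' The flagging threshold is \code{multiplier} times the null SD: with the
#' canonical SD of 0.2 and multiplier 2 this is the +/-0.4 log2 threshold,
#' beyond which about 5\% of null probes fall by chance.
#'
#' @param sd null standard deviation of the log2 ratios (>= 0).
#' @param multiplier threshold multiplier (default 2).
#' @return threshold in log2 units; zero thresholds carry attribute
#'   \code{degenerate = TRUE}.
#' @examples
#' derive_threshold(0.2, 2)  # 0.4
#' @export
derive_threshold <- function(sd, multiplier = 2) {
  stopifnot(sd >= 0, multiplier > 0)
  thr <- multiplier * sd
  if (thr == 0) attr(thr, "degenerate") <- TRUE
  thr
}

.profile_threshold <- function(profile, cfg) {
  if (!is.null(cfg$fixed_threshold)) return(abs(cfg$fixed_threshold))
  sd_est <- attr(profile, "sd_estimate")
  if (is.null(sd_est)) sd_est <- stats::mad(profile$log2_ratio)
  thr <- derive_threshold(sd_est, cfg$sd_multiplier)
  if (thr == 0) {
    stop("derived threshold is zero (constant profile); supply fixed_threshold",
         call. = FALSE)
  }
  as.numeric(thr)
}

# group flagged indices into runs separated by <= max_gap + 1 in index space
.flag_runs <- function(idx, max_gap) {
  if (!length(idx)) return(list())
  brk <- c(0L, which(diff(idx) > max_gap + 1L), length(idx))
  lapply(seq_len(length(brk) - 1L), function(i) idx[(brk[i] + 1L):brk[i + 1L]])
}

.segments_one_kind <- function(probes, flagged, kind, cfg) {
  runs <- .flag_runs(which(flagged), cfg$max_gap)
  runs <- runs[vapply(runs, length, integer(1)) >= cfg$k_consecutive]
  if (!length(runs)) return(NULL)
  do.call(rbind, lapply(runs, function(r) {
    data.frame(chrom = probes$chrom[r[1L]],
               start = probes$start[r[1L]],
               end = probes$end[r[length(r)]],
               kind = kind,
               n_probes = length(r),
               mean_ratio = mean(probes$log2_ratio[r]),
               first_probe = as.character(probes$probe_id[r[1L]]),
               last_probe = as.character(probes$probe_id[r[length(r)]]),
               stringsAsFactors = FALSE)
  }))
}

#' Call deletion/duplication segments by the consecutive-probe rule
#'
#' Flags probes whose log2 ratio is at or below minus the threshold
#' (deletion profile) or at or above plus the threshold (duplication
#' profile), and reports every maximal run of at least
#' \code{cfg$k_consecutive} flagged probes; runs are broken by more than
#' \code{cfg$max_gap} non-flagged probes and never span chromosomes. The
#' threshold is \code{cfg$fixed_threshold} if set, otherwise
#' \code{sd_multiplier} times the profile's robust SD
#' (see \code{\link{normalize_profile}}). Thresholds are inclusive
#' ("at or below").
#'
#' @param profile ratio profile, coordinate-sorted within each chromosome.
#' @param cfg a \code{\link{caller_config}}.
#' @return data.frame of segments: chrom, start, end (0-based half-open span
#'   from first to last flagged probe), kind, n_probes (flagged probes in the
#'   run), mean_ratio, first_probe, last_probe. Attribute \code{threshold}
#'   records the threshold used.
#' @export
call_segments <- function(profile, cfg = caller_config()) {
  stopifnot(all(c("chrom", "start", "end", "log2_ratio") %in% names(profile)))
  if (!"probe_id" %in% names(profile)) {
    profile$probe_id <- sprintf("p%d", seq_len(nrow(profile)))
  }
  thr <- .profile_threshold(profile, cfg)
  segs <- NULL
  for (ch in unique(profile$chrom)) {
    p <- profile[profile$chrom == ch, , drop = FALSE]
    if (is.unsorted(p$start)) {
      stop("probes are not coordinate-sorted on ", ch, call. = FALSE)
    }
    segs <- rbind(segs,
                  .segments_one_kind(p, p$log2_ratio <= -thr, "deletion", cfg),
                  .segments_one_kind(p, p$log2_ratio >= thr, "duplication", cfg))
  }
  if (is.null(segs)) {
    segs <- data.frame(chrom = character(), start = integer(), end = integer(),
                       kind = character(), n_probes = integer(),
                       mean_ratio = numeric(), first_probe = character(),
                       last_probe = character(), stringsAsFactors = FALSE)
  } else {
    segs <- segs[order(segs$chrom, segs$start), , drop = FALSE]
    rownames(segs) <- NULL
  }
  attr(segs, "threshold") <- thr
  segs
}

#' Feature-level deletion calls by probe fraction
#'
#' Implements the gene-model rule: a feature is called deleted when at least
#' \code{cfg$feature_fraction} (default 50\%) of the probes overlapping it
#' have log2 ratio at or below \code{cfg$feature_threshold} (default -0.8).
#' Boundaries are inclusive. Features covered by no probe yield NA with a
#' warning.
#'
#' @param profile ratio profile.
#' @param features data.frame of intervals (\code{chrom}, \code{start},
#'   \code{end} 0-based half-open; optional \code{feature_id}).
#' @param cfg a \code{\link{caller_config}}.
#' @return data.frame: feature_id, chrom, start, end, n_probes, n_below,
#'   fraction_below, called (logical, NA when no probes).
#' @export
feature_fraction_calls <- function(profile, features, cfg = caller_config()) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (!"feature_id" %in% names(features)) {
    features$feature_id <- sprintf("feature%d", seq_len(nrow(features)))
  }
  pr <- IRanges::IRanges(profile$start + 1L, profile$end)
  out <- lapply(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    hit <- profile$chrom == f$chrom &
      IRanges::overlapsAny(pr, IRanges::IRanges(f$start + 1L, f$end))
    n <- sum(hit)
    if (n == 0L) {
      warning("feature ", f$feature_id, " overlaps no probes; no call",
              call. = FALSE)
      return(data.frame(feature_id = f$feature_id, chrom = f$chrom,
                        start = f$start, end = f$end, n_probes = 0L,
                        n_below = NA_integer_, fraction_below = NA_real_,
                        called = NA, stringsAsFactors = FALSE))
    }
    n_below <- sum(profile$log2_ratio[hit] <= cfg$feature_threshold)
    frac <- n_below / n
    data.frame(feature_id = f$feature_id, chrom = f$chrom, start = f$start,
               end = f$end, n_probes = n, n_below = n_below,
               fraction_below = frac, called = frac >= cfg$feature_fraction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
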