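# Designed-vs-detected accounting and detection-power analysis.

.max_run <- function(flags) {
  if (!length(flags) || !any(flags)) return(0L)
  r <- rle(flags)
  max(r$lengths[r$values])
}

#' Designed vs detected probe accounting for one deletion
#'
#' For each staggered probe set in a profile, counts the probes that overlap
#' the deletion ("designed"), the designed probes whose log2 ratio falls at
#' or below minus the threshold ("detected"), the percent detected, and
#' whether the deletion is called under the k-consecutive rule evaluated
#' within the set.
#'
#' @param profile ratio profile whose probes carry \code{stagger} (and
#'   optionally \code{set_id}) columns; multiple sets may be pooled.
#' @param deletion interval (list/data.frame with \code{chrom}, \code{start},
#'   \code{end}).
#' @param cfg a \code{\link{caller_config}}; the threshold is
#'   \code{cfg$fixed_threshold} if set, otherwise derived from the profile's
#'   robust SD.
#' @return data.frame: set_id, stagger, n_designed, n_detected,
#'   percent_detected, called.
#' @export
designed_vs_detected <- function(profile, deletion, cfg = caller_config()) {
  stopifnot("stagger" %in% names(profile))
  thr <- .profile_threshold(profile, cfg)
  if (!"set_id" %in% names(profile) || all(is.na(profile$set_id))) {
    profile$set_id <- sprintf("s%d", profile$stagger)
  }
  sets <- split(seq_len(nrow(profile)), profile$set_id)
  out <- lapply(names(sets), function(sid) {
    p <- profile[sets[[sid]], , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    des <- p$chrom == deletion$chrom &
      p$start < deletion$end & p$end > deletion$start
    n_des <- sum(des)
    flagged <- p$log2_ratio[des] <= -thr
    n_det <- sum(flagged)
    data.frame(set_id = sid, stagger = p$stagger[1L], n_designed = n_des,
               n_detected = n_det,
               percent_detected = if (n_des) 100 * n_det / n_des else NA_real_,
               called = .max_run(flagged) >= cfg$k_consecutive,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$stagger), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Mean percent-detected across probe sets
#'
#' Unweighted mean of the per-set percent of designed probes showing a
#' deletion profile; sets with no designed probes are excluded.
#'
#' @param reports data.frame from \code{\link{designed_vs_detected}}.
#' @return mean percent (0-100).
#' @export
percent_detected_summary <- function(reports) {
  stopifnot(nrow(reports) >= 1L)
  mean(reports$percent_detected[reports$n_designed > 0L])
}

# simulate one replicate: designed probes of length L on an s-grid at the
# given phase across a deletion of size d at position D; returns TRUE when
# the k-consecutive rule calls the deletion within the set
.power_one <- function(d, L, s, phase, D, model, cfg, thr) {
  lo <- D - L + 1L
  first <- lo + ((phase - lo) %% s)
  starts <- seq.int(first, D + d - 1L, by = s)
  if (!length(starts)) return(FALSE)
  probes <- data.frame(probe_id = sprintf("p%d", seq_along(starts)),
                       chrom = "sim", start = starts, end = starts + L,
                       stringsAsFactors = FALSE)
  prof <- simulate_profile(probes,
                           data.frame(chrom = "sim", start = D, end = D + d,
                                      kind = "deletion", label = "del",
                                      stringsAsFactors = FALSE),
                           model, seed = NULL)
  .max_run(prof$log2_ratio <= -thr) >= cfg$k_consecutive
}

#' Detection power per stagger and minimum detectable stagger
#'
#' Estimates, for each candidate stagger, the probability that a deletion of
#' the given size is called under the k-consecutive rule, over random (or
#' exhaustively enumerated) grid phases and noise replicates drawn from the
#' model, and returns the largest stagger whose power reaches
#' \code{power_target}.
#'
#' @param deletion_size deletion size in bases.
#' @param model a \code{\link{noise_model}}.
#' @param cfg a \code{\link{caller_config}}; the flagging threshold is
#'   \code{cfg$fixed_threshold} if set, otherwise
#'   \code{cfg$sd_multiplier * model$null_sd}.
#' @param staggers candidate staggers, sorted ascending.
#' @param n_reps Monte-Carlo replicates per stagger (random-phase mode).
#' @param power_target required detection probability (default 0.95).
#' @param probe_len probe length in bases (default 50).
#' @param phases \code{"random"} (default): a uniform random phase per
#'   replicate; \code{"all"}: every phase 0..s-1 exactly once (deterministic
#'   in the noise-free limit).
#' @param seed integer seed.
#' @return the largest qualifying stagger as an integer, or \code{NA} with a
#'   message when no stagger reaches the target. The full power curve
#'   (data.frame stagger, power, n_reps) is attached as attribute
#'   \code{"power_curve"}.
#' @export
min_detectable_stagger <- function(deletion_size, model = noise_model(),
                                   cfg = caller_config(),
                                   staggers = design_config()$staggers,
                                   n_reps = 1000L, power_target = 0.95,
                                   probe_len = 50L,
                                   phases = c("random", "all"), seed = NULL) {
  phases <- match.arg(phases)
  staggers <- as.integer(staggers)
  stopifnot(!is.unsorted(staggers), n_reps >= 1L, deletion_size >= 1L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  d <- as.integer(deletion_size); L <- as.integer(probe_len)
  D <- 100000L
  thr <- if (!is.null(cfg$fixed_threshold)) abs(cfg$fixed_threshold) else
    derive_threshold(model$null_sd, cfg$sd_multiplier)
  power <- vapply(staggers, function(s) {
    ph <- if (phases == "all") 0:(s - 1L) else sample.int(s, n_reps, replace = TRUE) - 1L
    mean(vapply(ph, function(p) .power_one(d, L, s, p, D, model, cfg, thr),
                logical(1)))
  }, numeric(1))
  curve <- data.frame(stagger = staggers, power = power,
                      n_reps = if (phases == "all") staggers else n_reps)
  ok <- staggers[power >= power_target]
  res <- if (length(ok)) max(ok) else {
    message("no candidate stagger reaches power ", power_target)
    NA_integer_
  }
  structure(res, power_curve = curve, deletion_size = d, probe_len = L,
            power_target = power_target)
}

#' Published designed/detected table for the 104 bp deletion
#'
#' Loads the fixture table of the nineteen staggered probe sets over a 104 bp
#' deletion: per stagger, the number of probes designed across the deletion,
#' the number detected with log2 ratio at or below -0.4 in the single
#' reported hybridization, and the percent detected. The Detected column is
#' empirical single-array data and is shipped for comparison only.
#'
#' @return data.frame: stagger, designed, detected, percent.
#' @export
phyb104_table1 <- function() {
  path <- system.file("extdata", "phyb104_table1.tsv", package = "tilecgh",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
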