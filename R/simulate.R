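# Simulation of two-colour CGH log2-ratio profiles and synthetic references.

#' Noise model for simulated hybridizations
#'
#' Describes the per-probe signal model of a mutant-vs-control comparative
#' hybridization. Probes not overlapping any variant draw
#' Normal(0, \code{null_sd}). A probe overlapping a deletion "responds" with
#' probability \code{sensitivity}; a responding probe draws
#' Normal(mu, \code{del_sd}) where mu is \code{del_mean} for deletions
#' smaller than \code{large_cutoff} and \code{del_mean_large} otherwise
#' (small deletions hybridize at log2 ratios near -2, multi-kb deletions
#' near -6); a non-responding probe draws the null distribution. Probes over
#' duplications mirror the deletion means with positive sign. Under the
#' \code{"proportional"} response the deletion-channel mean is instead
#' \code{log2(1 - overlap_fraction + prop_eps)}, i.e. signal proportional to
#' the fraction of the probe lost.
#'
#' @param null_sd standard deviation of null probe log2 ratios (default 0.2).
#' @param del_mean mean log2 ratio of responding probes over small deletions
#'   (default -2).
#' @param del_mean_large mean for deletions of at least \code{large_cutoff}
#'   bases (default -6).
#' @param large_cutoff deletion size in bases separating the two regimes
#'   (default 1000).
#' @param del_sd standard deviation of responding-probe log2 ratios
#'   (default 0.5).
#' @param sensitivity probability a deletion-overlapping probe responds
#'   (default 0.94).
#' @param response \code{"empirical"} (default; any-overlap probes respond
#'   with the full deletion signal) or \code{"proportional"}.
#' @param prop_eps floor inside the proportional-response log (default 2^-6,
#'   so a fully deleted probe target gives log2 ratio -6).
#' @param fp_region_rate expected number of spurious variant-like regions per
#'   simulated genome (default 0).
#' @param fp_region_probes range of probes spanned by one spurious region
#'   (default 3 to 10).
#' @param seed optional integer seed recorded with the model.
#' @return list of class \code{"noise_model"}.
#' @export
noise_model <- function(null_sd = 0.2, del_mean = -2, del_mean_large = -6,
                        large_cutoff = 1000L, del_sd = 0.5,
                        sensitivity = 0.94,
                        response = c("empirical", "proportional"),
                        prop_eps = 2^-6, fp_region_rate = 0,
                        fp_region_probes = c(3L, 10L), seed = NULL) {
  stopifnot(null_sd > 0, del_sd >= 0, sensitivity >= 0, sensitivity <= 1,
            large_cutoff >= 1, fp_region_rate >= 0)
  if (del_mean >= -(2 * null_sd)) {
    stop("del_mean must lie below -2*null_sd (deletion signal must clear ",
         "the threshold regime)", call. = FALSE)
  }
  structure(list(null_sd = null_sd, del_mean = del_mean,
                 del_mean_large = del_mean_large,
                 large_cutoff = as.integer(large_cutoff), del_sd = del_sd,
                 sensitivity = sensitivity, response = match.arg(response),
                 prop_eps = prop_eps, fp_region_rate = fp_region_rate,
                 fp_region_probes = as.integer(fp_region_probes),
                 seed = seed),
            class = "noise_model")
}

.check_variants <- function(variants) {
  if (is.null(variants) || !nrow(as.data.frame(variants))) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      kind = character(), label = character(),
                      stringsAsFactors = FALSE))
  }
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (!"kind" %in% names(v)) v$kind <- "deletion"
  if (!"label" %in% names(v)) v$label <- sprintf("var%d", seq_len(nrow(v)))
  stopifnot(all(c("chrom", "start", "end") %in% names(v)))
  if (any(v$end <= v$start)) stop("variant intervals must have end > start", call. = FALSE)
  for (ch in unique(v$chrom)) {
    vi <- v[v$chrom == ch, , drop = FALSE]
    vi <- vi[order(vi$start), , drop = FALSE]
    if (nrow(vi) > 1L && any(vi$start[-1L] < vi$end[-nrow(vi)])) {
      stop("overlapping variant intervals on ", ch, call. = FALSE)
    }
  }
  v
}

.check_sorted_probes <- function(probes) {
  stopifnot(all(c("chrom", "start", "end") %in% names(probes)))
  for (ch in unique(probes$chrom)) {
    st <- probes$start[probes$chrom == ch]
    if (is.unsorted(st)) {
      stop("probes must be sorted by start within each chromosome", call. = FALSE)
    }
  }
  invisible(probes)
}

#' Simulate a per-probe log2-ratio profile
#'
#' Draws a normalized log2(mutant/control) value for every probe under a
#' \code{\link{noise_model}}, given the true variants carried by the mutant
#' genome. Reproducible given a seed.
#'
#' @param probes probe data.frame (needs \code{chrom}, \code{start},
#'   \code{end}; extra columns such as \code{probe_id}, \code{stagger},
#'   \code{set_id} are carried through), sorted by start within chromosome.
#' @param variants data.frame of variant intervals (\code{chrom},
#'   \code{start}, \code{end}, optional \code{kind} = "deletion"/"duplication"
#'   and \code{label}); intervals must not overlap. NULL for a null profile.
#' @param model a \code{\link{noise_model}}.
#' @param seed integer seed (default the model's seed); when non-NULL the
#'   global RNG is seeded so the profile is reproducible.
#' @return data.frame of class \code{"ratio_profile"}: the probe columns plus
#'   \code{log2_ratio}, with attributes \code{model}, \code{truth} and
#'   \code{seed}.
#' @export
simulate_profile <- function(probes, variants = NULL, model = noise_model(),
                             seed = model$seed) {
  if (inherits(probes, "staggered_probe_set")) probes <- probes$probes
  .check_sorted_probes(probes)
  variants <- .check_variants(variants)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(probes)
  ratio <- stats::rnorm(n, 0, model$null_sd)
  if (nrow(variants)) {
    pr <- IRanges::IRanges(probes$start + 1L, probes$end)
    for (vi in seq_len(nrow(variants))) {
      v <- variants[vi, ]
      on_chrom <- probes$chrom == v$chrom
      hit <- on_chrom & IRanges::overlapsAny(
        pr, IRanges::IRanges(v$start + 1L, v$end))
      idx <- which(hit)
      if (!length(idx)) next
      size <- v$end - v$start
      mu <- if (size >= model$large_cutoff) model$del_mean_large else model$del_mean
      if (model$response == "proportional") {
        ov <- pmin(probes$end[idx], v$end) - pmax(probes$start[idx], v$start)
        frac <- ov / (probes$end[idx] - probes$start[idx])
        mu <- log2(pmax(1 - frac, 0) + model$prop_eps)
      }
      if (v$kind == "duplication") mu <- -mu
      responds <- stats::runif(length(idx)) < model$sensitivity
      if (any(responds)) {
        ratio[idx[responds]] <- stats::rnorm(sum(responds),
                                             mu[if (length(mu) > 1L) responds else 1L],
                                             model$del_sd)
      }
    }
  }
  if (model$fp_region_rate > 0) {
    n_fp <- stats::rpois(1L, model$fp_region_rate)
    for (f in seq_len(n_fp)) {
      w <- sample(model$fp_region_probes[1L]:model$fp_region_probes[2L], 1L)
      if (n < w) next
      at <- sample.int(n - w + 1L, 1L)
      ratio[at:(at + w - 1L)] <- stats::rnorm(w, model$del_mean, model$del_sd)
    }
  }
  out <- probes
  out$log2_ratio <- ratio
  structure(out, model = model, truth = variants, seed = seed,
            class = c("ratio_profile", "data.frame"))
}

#' Simulate raw two-channel intensities
#'
#' Generates positive per-probe Cy3 (mutant) and Cy5 (control) intensities as
#' log-normal draws whose log2 ratio equals, probe for probe, the profile
#' produced by \code{\link{simulate_profile}} with the same seed.
#'
#' @inheritParams simulate_profile
#' @param base_log2_mean,base_log2_sd mean and SD of the control channel's
#'   log2 intensity (defaults 10 and 1).
#' @return data.frame with the probe columns, \code{intensity_mutant},
#'   \code{intensity_control} and \code{log2_ratio}.
#' @export
simulate_two_channel <- function(probes, variants = NULL,
                                 model = noise_model(), seed = model$seed,
                                 base_log2_mean = 10, base_log2_sd = 1) {
  prof <- simulate_profile(probes, variants, model, seed)
  base <- stats::rnorm(nrow(prof), base_log2_mean, base_log2_sd)
  out <- as.data.frame(prof)
  out$intensity_control <- 2^base
  out$intensity_mutant <- 2^(base + prof$log2_ratio)
  attr(out, "model") <- model
  attr(out, "seed") <- seed
  out
}

#' Generate a synthetic reference sequence
#'
#' Random DNA with a given GC fraction, optionally with exact-copy repeated
#' blocks (to exercise probe uniqueness filtering). Reproducible given a
#' seed.
#'
#' @param length sequence length in bases.
#' @param gc_fraction expected fraction of G+C (default 0.36, typical of a
#'   small plant genome).
#' @param repeat_spec optional list of repeats, each a list with \code{from}
#'   (0-based source start), \code{width}, and \code{to} (vector of 0-based
#'   destination starts receiving exact copies of the source block).
#' @param seed integer seed.
#' @param name sequence name (default "chr1").
#' @return a named \code{DNAStringSet} of length one.
#' @export
generate_synthetic_reference <- function(length, gc_fraction = 0.36,
                                         repeat_spec = NULL, seed = NULL,
                                         name = "chr1") {
  stopifnot(length >= 1, gc_fraction >= 0, gc_fraction <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = p)
  for (rp in repeat_spec) {
    block <- bases[(rp$from + 1L):(rp$from + rp$width)]
    for (dest in rp$to) {
      stopifnot(dest + rp$width <= length)
      bases[(dest + 1L):(dest + rp$width)] <- block
    }
  }
  out <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(out) <- name
  out
}
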