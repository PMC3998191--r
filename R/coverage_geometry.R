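# Coverage geometry of staggered probe sets.
#
# The central identity: a probe of length L overlaps a deletion of size d by
# at least m bases iff its start lies in a window of width d + L - 2m + 1
# (for the default m = 1, width d + L - 1). On a start grid of spacing s the
# number of grid points in that window is floor(w/s) or floor(w/s) + 1
# depending on the grid phase.

# number of integers congruent to phase (mod s) in [lo, hi]
.grid_count <- function(lo, hi, s, phase) {
  if (hi < lo) return(0L)
  as.integer(floor((hi - phase) / s) - ceiling((lo - phase) / s) + 1L)
}

#' Probes of a staggered set overlapping a deletion
#'
#' Counts, for a staggered probe grid or an explicit probe set, the probes
#' overlapping a deletion interval ("designed" probes), the probes fully
#' containing it, the probes fully contained in it, and the maximum per-base
#' coverage depth inside the deletion.
#'
#' Two input forms are supported: an explicit \code{staggered_probe_set} (or
#' probe data.frame), in which case counts are computed by interval overlap
#' on the actual probes; or the parametric form \code{(L, s, phase)}
#' describing the infinite grid of length-L probes with starts congruent to
#' \code{phase} modulo \code{s}.
#'
#' @param set a \code{staggered_probe_set} or probe data.frame, or NULL to
#'   use the parametric form.
#' @param del deletion interval: list or data.frame with \code{start},
#'   \code{end} (0-based half-open), optionally \code{chrom}.
#' @param L,s,phase parametric form: probe length, stagger, and grid phase
#'   (starts are \code{phase + i*s}).
#' @param min_overlap minimum shared bases for a probe to count as
#'   overlapping (default 1).
#' @return list of class \code{"coverage_summary"} with \code{n_overlapping},
#'   \code{n_fully_within_probe}, \code{n_probe_within_deletion},
#'   \code{max_depth}.
#' @examples
#' count_overlapping(L = 50, s = 17, phase = 0,
#'                   del = list(start = 1000, end = 1104))
#' @export
count_overlapping <- function(set = NULL, del, L = NULL, s = NULL, phase = 0L,
                              min_overlap = 1L) {
  d_start <- as.integer(del$start); d_end <- as.integer(del$end)
  if (d_end <= d_start) stop("deletion interval must have end > start", call. = FALSE)
  d <- d_end - d_start
  m <- as.integer(min_overlap)
  stopifnot(m >= 1L)
  if (!is.null(set)) {
    probes <- if (inherits(set, "staggered_probe_set")) set$probes else set
    if (!is.null(del$chrom) && "chrom" %in% names(probes)) {
      probes <- probes[probes$chrom == del$chrom, , drop = FALSE]
    }
    pr <- IRanges::IRanges(start = probes$start + 1L, end = probes$end)
    dr <- IRanges::IRanges(start = d_start + 1L, end = d_end)
    ov <- IRanges::countOverlaps(pr, dr, minoverlap = m)
    inside <- pr[ov > 0L]
    n_over <- sum(ov > 0L)
    n_del_in_probe <- sum(probes$start <= d_start & probes$end >= d_end)
    n_probe_in_del <- sum(probes$start >= d_start & probes$end <= d_end)
    depth <- if (n_over) max(S4Vectors::runValue(
      IRanges::coverage(inside)[(d_start + 1L):d_end])) else 0L
  } else {
    stopifnot(!is.null(L), !is.null(s))
    L <- as.integer(L); s <- as.integer(s); phase <- as.integer(phase)
    stopifnot(L >= 1L, s >= 1L)
    n_over <- .grid_count(d_start - L + m, d_end - m, s, phase)
    n_del_in_probe <- if (L >= d) {
      .grid_count(d_end - L, d_start, s, phase)
    } else 0L
    n_probe_in_del <- if (d >= L) {
      .grid_count(d_start, d_end - L, s, phase)
    } else 0L
    # depth is periodic in the position with period s
    pos <- d_start + seq_len(min(d, s)) - 1L
    depth <- max(vapply(pos, function(x) {
      .grid_count(x - L + 1L, x, s, phase)
    }, integer(1)))
  }
  structure(list(n_overlapping = as.integer(n_over),
                 n_fully_within_probe = as.integer(n_del_in_probe),
                 n_probe_within_deletion = as.integer(n_probe_in_del),
                 max_depth = as.integer(depth)),
            class = "coverage_summary")
}

#' Per-base coverage depth of a staggered probe grid
#'
#' Number of length-\code{L} probes on a stagger-\code{s} grid covering a
#' single genomic position. Depth is \code{floor(L/s)} or \code{ceiling(L/s)}
#' depending on the position relative to the grid phase, and is exactly
#' \code{L/s} for every position when \code{s} divides \code{L} (e.g. 74-mers
#' staggered every 2 bp cover every base 37 times; 50-mers staggered every
#' 25 bp — conventional partially overlapping tiling — cover every base
#' twice).
#'
#' @param L probe length in bases.
#' @param s stagger in bases.
#' @param position 0-based genomic position (default 0).
#' @param phase grid phase: probe starts are congruent to \code{phase} mod
#'   \code{s} (default 0).
#' @return integer coverage depth.
#' @examples
#' per_base_depth(74, 2)   # 37
#' per_base_depth(50, 25)  # 2
#' per_base_depth(50, 50)  # 1
#' @export
per_base_depth <- function(L, s, position = 0L, phase = 0L) {
  L <- as.integer(L); s <- as.integer(s)
  position <- as.integer(position); phase <- as.integer(phase)
  stopifnot(L >= 1L, s >= 1L)
  .grid_count(position - L + 1L, position, s, phase)
}

#' Largest stagger guaranteeing k probes across a deletion
#'
#' Returns the largest stagger \code{s} such that, for every grid phase, at
#' least \code{k} probes of length \code{L} overlap a deletion of size
#' \code{d} by at least one base. Since the worst-phase overlap count is
#' \code{floor((d + L - 1)/s)}, the answer is \code{floor((d + L - 1)/k)}.
#'
#' @param d deletion size in bases.
#' @param L probe length in bases.
#' @param k required number of overlapping probes.
#' @return integer stagger in bases.
#' @examples
#' max_stagger_guaranteeing_k(104, 50, 3)  # 51
#' @export
max_stagger_guaranteeing_k <- function(d, L, k) {
  d <- as.integer(d); L <- as.integer(L); k <- as.integer(k)
  stopifnot(d >= 1L, L >= 1L, k >= 1L)
  w <- d + L - 1L
  if (k > w) {
    stop("no stagger can guarantee ", k, " overlapping probes: the start ",
         "window holds at most ", w, " probes (d + L - 1)", call. = FALSE)
  }
  w %/% k
}
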