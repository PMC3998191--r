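# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# naive run scanner (max_gap = 0): explicit consecutive runs of flagged
# probes, kept when at least k long
brute_force_runs_nogap <- function(flags, k) {
  runs <- list()
  cur <- integer()
  for (i in seq_along(flags)) {
    if (flags[i]) {
      cur <- c(cur, i)
    } else {
      if (length(cur) >= k) runs[[length(runs) + 1L]] <- cur
      cur <- integer()
    }
  }
  if (length(cur) >= k) runs[[length(runs) + 1L]] <- cur
  runs
}

# brute-force segment table from a profile data.frame (single chromosome)
brute_force_segments <- function(profile, threshold, k) {
  segs <- NULL
  for (kind in c("deletion", "duplication")) {
    flags <- if (kind == "deletion") profile$log2_ratio <= -threshold
             else profile$log2_ratio >= threshold
    for (r in brute_force_runs_nogap(flags, k)) {
      segs <- rbind(segs, data.frame(
        start = profile$start[r[1L]], end = profile$end[r[length(r)]],
        kind = kind, n_probes = length(r),
        mean_ratio = mean(profile$log2_ratio[r]),
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(segs)) return(segs)
  segs <- segs[order(segs$start, segs$kind), , drop = FALSE]
  rownames(segs) <- NULL
  segs
}

# naive all-substring occurrence count (both strands) in a character vector
# of chromosome sequences; overlapping matches counted
naive_hit_count <- function(probe_seq, chrom_seqs) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(probe_seq)))
  pats <- unique(c(probe_seq, rc))
  total <- 0L
  for (chrom in chrom_seqs) {
    n <- nchar(chrom)
    w <- nchar(probe_seq)
    for (pat in pats) {
      for (i in seq_len(n - w + 1L)) {
        if (substr(chrom, i, i + w - 1L) == pat) total <- total + 1L
      }
    }
  }
  total
}

# explicit enumeration of probe starts on a stagger grid overlapping a
# deletion by >= m bases (wide safety margin around the window)
enumerate_overlap_counts <- function(L, s, phase, d_start, d_end, m = 1L) {
  starts <- seq.int(phase - (abs(d_start) %/% s + 100L) * s,
                    d_end + 100L * s, by = s)
  p_end <- starts + L
  ov <- pmin(p_end, d_end) - pmax(starts, d_start)
  list(n_overlapping = sum(ov >= m),
       n_fully_within_probe = sum(starts <= d_start & p_end >= d_end),
       n_probe_within_deletion = sum(starts >= d_start & p_end <= d_end))
}

# fixed-length probe grid as a probe data.frame
make_probe_grid <- function(chrom = "chr1", from, to, stagger, L = 50L) {
  starts <- seq.int(from, to, by = stagger)
  data.frame(probe_id = sprintf("%s_p%d", chrom, seq_along(starts)),
             chrom = chrom, start = starts, end = starts + L,
             stagger = as.integer(stagger),
             set_id = sprintf("s%d", stagger), stringsAsFactors = FALSE)
}
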