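# Top-level pipeline: design -> simulate -> call -> power.

#' Run the full design/simulate/call/power pipeline
#'
#' Designs staggered probe sets over a region of the reference, simulates a
#' mutant-vs-control hybridization carrying the given variants, normalizes
#' and calls deletion/duplication segments, and produces the per-stagger
#' designed-vs-detected report for each deletion. All artifacts are written
#' under \code{out_dir}; inputs are never modified.
#'
#' @param ref reference: path to a FASTA file or a \code{DNAStringSet}.
#' @param region list with \code{chrom}, \code{start}, \code{end} (0-based
#'   half-open); default spans the first reference sequence.
#' @param variants data.frame of true variants (chrom, start, end, kind,
#'   label), or a BED path.
#' @param design_cfg a \code{\link{design_config}}.
#' @param model a \code{\link{noise_model}}.
#' @param caller_cfg a \code{\link{caller_config}}.
#' @param seed integer seed governing all randomness in the run.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with the design, profile, segment calls, reports
#'   and the paths of all written artifacts.
#' @export
pipeline_run <- function(ref, region = NULL, variants = NULL,
                         design_cfg = design_config(),
                         model = noise_model(),
                         caller_cfg = caller_config(),
                         seed = 1L, out_dir = tempfile("tilecgh_run_")) {
  if (is.character(ref)) ref <- read_fasta(ref)
  ref <- .as_reference(ref)
  if (is.null(region)) {
    region <- list(chrom = names(ref)[1L], start = 0L,
                   end = length(ref[[1L]]))
  }
  if (is.character(variants)) variants <- read_bed(variants)
  variants <- .check_variants(variants)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  design <- design_probe_sets(ref, region$chrom, region$start, region$end,
                              design_cfg)
  probes <- design$probes[order(design$probes$chrom, design$probes$start,
                                design$probes$set_id), ]
  message(sprintf("design: %d probes in %d sets (%d removed)",
                  nrow(probes), nrow(design$manifest),
                  sum(design$manifest$n_removed)))
  paths$probes_bed <- file.path(out_dir, "probes.bed")
  write_probe_bed(probes, paths$probes_bed)
  paths$probes_fasta <- file.path(out_dir, "probes.fasta")
  seqs <- Biostrings::DNAStringSet(probes$sequence)
  names(seqs) <- probes$probe_id
  write_fasta(seqs, paths$probes_fasta)
  paths$manifest <- file.path(out_dir, "design_manifest.tsv")
  .write_tsv(design$manifest, paths$manifest)

  model$seed <- as.integer(seed)
  profile <- simulate_profile(probes, variants, model)
  message(sprintf("simulate: %d probe ratios, %d true variants",
                  nrow(profile), nrow(variants)))
  paths$ratios <- file.path(out_dir, "ratios.tsv")
  write_ratio_tsv(profile, paths$ratios)
  if (nrow(variants)) {
    paths$truth_bed <- file.path(out_dir, "truth.bed")
    write_bed(data.frame(chrom = variants$chrom, start = variants$start,
                         end = variants$end, name = variants$label,
                         stringsAsFactors = FALSE), paths$truth_bed)
  }

  norm <- normalize_profile(profile)
  calls <- call_segments(norm, caller_cfg)
  message(sprintf("call: %d segments at threshold %.3f",
                  nrow(calls), attr(calls, "threshold")))
  paths$calls_bed <- file.path(out_dir, "calls.bed")
  if (nrow(calls)) {
    write_bed(data.frame(chrom = calls$chrom, start = calls$start,
                         end = calls$end, name = calls$kind,
                         score = as.integer(round(-100 * calls$mean_ratio)),
                         stringsAsFactors = FALSE), paths$calls_bed)
  } else {
    file.create(paths$calls_bed)
  }
  paths$calls_tsv <- file.path(out_dir, "calls.tsv")
  .write_tsv(calls, paths$calls_tsv)

  dels <- variants[variants$kind == "deletion", , drop = FALSE]
  reports <- lapply(seq_len(nrow(dels)), function(i) {
    r <- designed_vs_detected(norm, dels[i, ], caller_cfg)
    r$deletion <- dels$label[i]
    r
  })
  reports <- if (length(reports)) do.call(rbind, reports) else NULL
  if (!is.null(reports)) {
    paths$report <- file.path(out_dir, "designed_vs_detected.tsv")
    .write_tsv(reports, paths$report)
  }

  paths$metadata <- file.path(out_dir, "run_metadata.txt")
  write_metadata(list(
    toolkit = paste0("tilecgh ",
                     as.character(utils::packageVersion("tilecgh"))),
    seed = seed, chrom = region$chrom, region_start = region$start,
    region_end = region$end, staggers = design_cfg$staggers,
    min_len = design_cfg$min_len, max_len = design_cfg$max_len,
    target_tm = design_cfg$target_tm, null_sd = model$null_sd,
    sensitivity = model$sensitivity, response = model$response,
    sd_multiplier = caller_cfg$sd_multiplier,
    k_consecutive = caller_cfg$k_consecutive,
    n_probes = nrow(probes), n_variants = nrow(variants),
    n_calls = nrow(calls)), paths$metadata)

  invisible(list(design = design, profile = profile, calls = calls,
                 reports = reports, paths = paths, out_dir = out_dir))
}
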