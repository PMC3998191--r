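# Melting temperature of DNA oligonucleotides.
#
# Nearest-neighbor duplex thermodynamics, unified oligonucleotide parameter
# set of Allawi & SantaLucia (1997): dH in kcal/mol, dS in cal/(mol K) per
# dinucleotide step, plus terminal initiation terms.

.NN_STEPS <- local({
  dh <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
          CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
          CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
          CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
  ds <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
          CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
          CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
          CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
  list(dh = dh, ds = ds)
})

# terminal initiation: per A/T end and per G/C end
.NN_INIT <- list(AT = c(dh = 2.3, ds = 4.1), GC = c(dh = 0.1, ds = -2.8))

.GAS_CONSTANT <- 1.987 # cal/(mol K)

.check_dna <- function(sequence) {
  bad <- grepl("[^ACGT]", sequence)
  if (any(bad)) {
    stop("invalid sequence: non-ACGT character in ",
         paste(substr(sequence[bad], 1L, 20L), collapse = ", "), call. = FALSE)
  }
  invisible(sequence)
}

#' Reverse complement of a DNA string
#'
#' @param sequence character vector of A/C/G/T strings.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(sequence)))
}

.tm_nn_chars <- function(chars, na_mM, oligo_nM) {
  n <- length(chars)
  steps <- paste0(chars[-n], chars[-1L])
  dh <- sum(.NN_STEPS$dh[steps])
  ds <- sum(.NN_STEPS$ds[steps])
  for (end in chars[c(1L, n)]) {
    init <- if (end %in% c("A", "T")) .NN_INIT$AT else .NN_INIT$GC
    dh <- dh + init[["dh"]]
    ds <- ds + init[["ds"]]
  }
  ds <- ds + 0.368 * (n - 1L) * log(na_mM / 1000)
  1000 * dh / (ds + .GAS_CONSTANT * log(oligo_nM * 1e-9)) - 273.15
}

.tm_gc_chars <- function(chars) {
  64.9 + 41 * (sum(chars %in% c("G", "C")) - 16.4) / length(chars)
}

#' Oligonucleotide melting temperature
#'
#' Estimates the duplex melting temperature of a probe sequence. The default
#' method is nearest-neighbor thermodynamics with the unified parameter set of
#' Allawi & SantaLucia (1997), an entropy salt correction of
#' 0.368 (N-1) ln[Na+], and a duplex concentration term; the \code{"gc"}
#' method is the classic GC/length approximation
#' 64.9 + 41 (nGC - 16.4) / N, useful as a fast fallback.
#'
#' Both methods are deterministic, monotone non-decreasing in GC count at
#' fixed length, and invariant under reverse complementation (the duplex is
#' the same molecule read from the other strand).
#'
#' @param sequence character vector of A/C/G/T sequences (case-insensitive).
#' @param method \code{"nn"} (nearest-neighbor, default) or \code{"gc"}.
#' @param na_mM monovalent cation concentration in mM (default 50).
#' @param oligo_nM effective duplex concentration in nM (default 12.5).
#' @return numeric vector of melting temperatures in degrees Celsius.
#' @examples
#' compute_tm(strrep("ACGT", 15))
#' compute_tm("ACGTACGTACGTACGTACGT", method = "gc")
#' @export
compute_tm <- function(sequence, method = c("nn", "gc"), na_mM = 50,
                       oligo_nM = 12.5) {
  method <- match.arg(method)
  sequence <- toupper(sequence)
  if (any(!nzchar(sequence))) stop("invalid sequence: empty string", call. = FALSE)
  .check_dna(sequence)
  vapply(strsplit(sequence, "", fixed = TRUE), function(chars) {
    if (method == "nn") .tm_nn_chars(chars, na_mM, oligo_nM) else .tm_gc_chars(chars)
  }, numeric(1))
}

# Tm of every prefix of `chars` with length in [min_len, max_len].
# Shared-prefix cumulative sums keep isothermal probe search O(max_len)
# per start instead of O(max_len^2).
.tm_prefixes <- function(chars, min_len, max_len, method = "nn",
                         na_mM = 50, oligo_nM = 12.5) {
  lens <- min_len:max_len
  if (method == "gc") {
    gc_cum <- cumsum(chars %in% c("G", "C"))
    return(64.9 + 41 * (gc_cum[lens] - 16.4) / lens)
  }
  n <- length(chars)
  steps <- paste0(chars[-n], chars[-1L])
  dh_cum <- c(0, cumsum(.NN_STEPS$dh[steps]))
  ds_cum <- c(0, cumsum(.NN_STEPS$ds[steps]))
  init5 <- if (chars[1L] %in% c("A", "T")) .NN_INIT$AT else .NN_INIT$GC
  at3 <- chars[lens] %in% c("A", "T")
  dh <- dh_cum[lens] + init5[["dh"]] +
    ifelse(at3, .NN_INIT$AT[["dh"]], .NN_INIT$GC[["dh"]])
  ds <- ds_cum[lens] + init5[["ds"]] +
    ifelse(at3, .NN_INIT$AT[["ds"]], .NN_INIT$GC[["ds"]]) +
    0.368 * (lens - 1L) * log(na_mM / 1000)
  1000 * dh / (ds + .GAS_CONSTANT * log(oligo_nM * 1e-9)) - 273.15
}
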