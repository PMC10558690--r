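#' Standard amino-acid alphabet
#'
#' The 20 standard residues in alphabetical one-letter order. All positional
#' statistics in the package (column frequencies, KLD, scales) are restricted
#' to this alphabet; nonstandard letters are treated like gaps.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# one fixed codon per residue (common E. coli codons); a fixed back-translation
# keeps junction k-mers unambiguous and read mapping deterministic
CODON_TABLE <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
  G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
  M = "ATG", N = "AAT", P = "CCG", Q = "CAA", R = "CGT",
  S = "TCT", T = "ACC", V = "GTG", W = "TGG", Y = "TAT")

#' Background amino-acid frequencies
#'
#' `swissprot_background()` returns the amino-acid composition of the
#' UniProtKB/Swiss-Prot database (release statistics), normalized to sum to 1;
#' this is the default reference measure for the positional
#' conservation divergence. `uniform_background()` returns the uniform
#' distribution over the 20 standard residues, convenient for tests and for
#' checking analytic values.
#'
#' @return Named numeric vector over [AA_STANDARD], positive, summing to 1.
#' @export
swissprot_background <- function() {
  x <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37,
         Q = 3.93, E = 6.75, G = 7.07, H = 2.27, I = 5.96,
         L = 9.66, K = 5.84, M = 2.42, F = 3.86, P = 4.70,
         S = 6.56, T = 5.34, W = 1.08, Y = 2.92, V = 6.87)
  x <- x[AA_STANDARD]
  x / sum(x)
}

#' @rdname swissprot_background
#' @export
uniform_background <- function() {
  setNames(rep(1 / 20, 20), AA_STANDARD)
}

#' Built-in amino-acid scales
#'
#' Returns the bundled amino-acid scale tables used as default numeric
#' residue features: the Kyte-Doolittle hydropathy index and a synthetic
#' linker-propensity scale. The latter is a constructed placeholder that
#' encodes the qualitative pattern of inter-domain linker composition
#' (enrichment of P/G/S/T/Q, depletion of hydrophobics); it is labelled
#' synthetic and can be replaced by any AAindex-format table via
#' [read_aaindex()].
#'
#' @return Named list of named numeric vectors over [AA_STANDARD].
#' @export
default_scales <- function() {
  path <- system.file("extdata", "aa_scales.aaindex", package = "inserttol")
  read_aaindex(path)
}

#' Read amino-acid scales in AAindex format
#'
#' Parses a flat file of AAindex-style entries (`H` accession, `D`
#' description, `I` header followed by two rows of ten values in
#' A R N D C Q E G H I / L K M F P S T W Y V order, `//` terminator).
#'
#' @param path Path to an AAindex-format file.
#' @return Named list (by accession) of named numeric vectors over
#'   [AA_STANDARD].
#' @export
read_aaindex <- function(path) {
  if (!file.exists(path)) {
    it_stop(sprintf("AAindex file '%s' does not exist", path), "parse_error")
  }
  lines <- readLines(path)
  aaindex_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                     "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  scales <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (startsWith(lines[i], "H ")) {
      acc <- trimws(sub("^H ", "", lines[i]))
      j <- i
      while (j <= length(lines) && !startsWith(lines[j], "I ")) j <- j + 1L
      if (j + 2L > length(lines)) {
        it_stop(sprintf("truncated AAindex entry '%s'", acc), "parse_error")
      }
      vals <- as.numeric(unlist(strsplit(trimws(lines[c(j + 1L, j + 2L)]),
                                         "[[:space:]]+")))
      if (length(vals) != 20L || anyNA(vals)) {
        it_stop(sprintf("AAindex entry '%s' does not contain 20 values", acc),
                "parse_error")
      }
      v <- setNames(vals, aaindex_order)[AA_STANDARD]
      scales[[acc]] <- v
      i <- j + 3L
    } else {
      i <- i + 1L
    }
  }
  if (!length(scales)) it_stop("no AAindex entries found", "parse_error")
  scales
}
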