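#' Count silk repeat motifs in a protein sequence
#'
#' Counts poly-alanine runs and the glycine-rich motifs GGX and GPGXX
#' (X = any residue). Poly-A counts maximal runs of 'A' of length at least
#' `polya_min`. GGX and GPGXX are counted as non-overlapping matches in a
#' single left-to-right scan in which the longer motif takes precedence: a
#' GPGXX match consumes its five residues, so no GGX is counted inside it.
#'
#' @param seq character amino-acid sequence (uppercase one-letter code), or
#'   a list/data.frame with a `sequence` field.
#' @param polya_min minimal poly-alanine run length (default 4).
#' @return named integer vector `c(polyA=, GGX=, GPGXX=)`.
#' @export
count_repeat_motifs <- function(seq, polya_min = 4) {
  seq <- .get_sequence(seq)
  n <- nchar(seq)
  runs <- gregexpr(sprintf("A{%d,}", polya_min), seq)[[1]]
  polya <- if (runs[1] == -1) 0L else length(runs)
  ggx <- 0L; gpgxx <- 0L
  ch <- strsplit(seq, "")[[1]]
  i <- 1L
  while (i <= n - 2L) {
    if (i + 4L <= n && ch[i] == "G" && ch[i + 1L] == "P" && ch[i + 2L] == "G") {
      gpgxx <- gpgxx + 1L
      i <- i + 5L
    } else if (ch[i] == "G" && ch[i + 1L] == "G") {
      ggx <- ggx + 1L
      i <- i + 3L
    } else i <- i + 1L
  }
  c(polyA = polya, GGX = ggx, GPGXX = gpgxx)
}

#' Amino-acid category composition
#'
#' Fraction of residues in four categories: small nonpolar (A, G, P, S, T),
#' hydrophobic (I, L, M, V), polar (D, E, H, K, N, Q, R), and aromatic and
#' cysteine (C, F, W, Y). 'X' residues are excluded from the denominator
#' with a warning.
#'
#' @param seq character amino-acid sequence or record with a `sequence`
#'   field.
#' @return named numeric vector of four fractions summing to 1.
#' @export
aa_category_composition <- function(seq) {
  seq <- .get_sequence(seq)
  cats <- list(small_nonpolar = c("A", "G", "P", "S", "T"),
               hydrophobic = c("I", "L", "M", "V"),
               polar = c("D", "E", "H", "K", "N", "Q", "R"),
               aromatic_cysteine = c("C", "F", "W", "Y"))
  ch <- strsplit(seq, "")[[1]]
  if (any(ch == "X")) {
    .warnf("%d 'X' residue(s) excluded from the composition denominator",
           sum(ch == "X"))
    ch <- ch[ch != "X"]
  }
  bad <- setdiff(unique(ch), unlist(cats))
  if (length(bad)) .stopf("non-standard residue(s): %s", paste(bad, collapse = ", "))
  n <- length(ch)
  vapply(cats, function(cc) sum(ch %in% cc) / n, numeric(1))
}

.get_sequence <- function(seq) {
  if (is.list(seq) || is.data.frame(seq)) seq <- seq$sequence
  seq <- as.character(seq)
  if (length(seq) != 1 || is.na(seq) || !nzchar(seq))
    .stopf("a single nonempty sequence is required")
  seq
}

#' Per-protein sequence feature table
#'
#' Motif counts and category composition for a set of protein sequences.
#'
#' @param seqs named character vector of sequences.
#' @param polya_min minimal poly-alanine run (default 4).
#' @return data.frame with one row per protein.
#' @export
sequence_feature_table <- function(seqs, polya_min = 4) {
  rows <- lapply(names(seqs), function(id) {
    m <- count_repeat_motifs(seqs[[id]], polya_min)
    comp <- suppressWarnings(aa_category_composition(seqs[[id]]))
    data.frame(protein = id, length = nchar(seqs[[id]]),
               polyA = m[["polyA"]], GGX = m[["GGX"]], GPGXX = m[["GPGXX"]],
               t(comp), row.names = NULL)
  })
  do.call(rbind, rows)
}
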