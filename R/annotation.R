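# Serpin sequence features: hinge-region alanine motif, P1/P1' transfer
# through a pairwise alignment, and covalent-complex mass arithmetic.
# All residue coordinates are 1-based inclusive.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

# average residue masses (kD): monoisotopic-free average amino-acid masses
# minus one water, i.e. the mass each residue contributes inside a chain
AA_RESIDUE_KD <- c(
  A = 0.0710788, R = 0.1561875, N = 0.1141038, D = 0.1150886,
  C = 0.1031388, E = 0.1291155, Q = 0.1281307, G = 0.0570519,
  H = 0.1371411, I = 0.1131594, L = 0.1131594, K = 0.1281741,
  M = 0.1311926, F = 0.1471766, P = 0.0971167, S = 0.0870782,
  T = 0.1011051, W = 0.1862132, Y = 0.1631760, V = 0.0991326,
  X = 0.110)

#' Serpin amino-acid sequence with optional site annotations
#'
#' @param id Sequence identifier.
#' @param residues One-letter amino-acid string (20-letter alphabet plus X).
#' @param hinge Optional hinge window, `c(start, end)` 1-based inclusive.
#' @param p1 Optional P1 index (residue N-terminal of the scissile bond);
#'   P1' is always `p1 + 1`.
#' @return An object of class `serpin_sequence`.
#' @export
serpin_sequence <- function(id, residues, hinge = NULL, p1 = NULL) {
  residues <- toupper(gsub("[[:space:]]", "", residues))
  chars <- strsplit(residues, "")[[1L]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0L)
    stop("invalid residue letters: ", paste(bad, collapse = ", "))
  len <- length(chars)
  if (!is.null(hinge)) {
    stopifnot(length(hinge) == 2L)
    if (hinge[1L] < 1L || hinge[1L] > hinge[2L] || hinge[2L] > len)
      stop("hinge window out of range")
  }
  if (!is.null(p1) && (p1 < 1L || p1 + 1L > len))
    stop("P1 must satisfy 1 <= P1 < length (P1' = P1 + 1 must exist)")
  structure(list(id = id, residues = residues, length = len,
                 hinge = hinge, p1 = p1),
            class = "serpin_sequence")
}

#' @export
print.serpin_sequence <- function(x, ...) {
  cat(sprintf(">%s (%d aa)\n", x$id, x$length))
  if (!is.null(x$hinge))
    cat(sprintf("  hinge: %d-%d (%s)\n", x$hinge[1L], x$hinge[2L],
                substr(x$residues, x$hinge[1L], x$hinge[2L])))
  if (!is.null(x$p1))
    cat(sprintf("  P1/P1': %s%d / %s%d\n",
                substr(x$residues, x$p1, x$p1), x$p1,
                substr(x$residues, x$p1 + 1L, x$p1 + 1L), x$p1 + 1L))
  invisible(x)
}

#' Read serpin sequences from a FASTA file
#'
#' @param path FASTA file of amino-acid sequences.
#' @return A list of [serpin_sequence] objects.
#' @export
read_serpin_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package")
  aa <- Biostrings::readAAStringSet(path)
  mapply(function(nm, s) serpin_sequence(sub("\\s.*$", "", nm), s),
         names(aa), as.character(aa), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Scan for the hinge-region small-residue motif
#'
#' Inhibitory serpins carry an alanine-rich hinge in the reactive center
#' loop (consensus exemplified by ATAATA). Every window of `window`
#' residues is scored as the count of alanines plus half the count of the
#' other small residues (G, S, T); windows scoring at least `threshold`
#' are reported, sorted by score then position.
#'
#' @param seq A [serpin_sequence] (or a plain residue string).
#' @param window Window length (default 6).
#' @param threshold Minimum reported score (default 4).
#' @param full_residues Residues counted with weight 1 (default `"A"`).
#' @param half_residues Residues counted with weight 0.5 (default G, S, T).
#' @return Data frame with columns `start`, `end` (1-based inclusive) and
#'   `score`; zero rows when nothing passes.
#' @export
find_hinge_motif <- function(seq, window = 6L, threshold = 4,
                             full_residues = "A",
                             half_residues = c("G", "S", "T")) {
  if (is.character(seq)) seq <- serpin_sequence("query", seq)
  stopifnot(inherits(seq, "serpin_sequence"))
  if (seq$length < window)
    stop("sequence shorter than the scan window (", window, ")")
  chars <- strsplit(seq$residues, "")[[1L]]
  w <- as.numeric(chars %in% full_residues) +
    0.5 * as.numeric(chars %in% half_residues)
  score <- as.numeric(stats::filter(w, rep(1, window), sides = 1))
  score <- score[window:seq$length]  # score[i] is window starting at i
  starts <- seq_len(seq$length - window + 1L)
  hit <- score >= threshold
  out <- data.frame(start = starts[hit], end = starts[hit] + window - 1L,
                    score = score[hit])
  out[order(-out$score, out$start), , drop = FALSE]
}

#' Transfer a P1 site from a reference serpin through an alignment
#'
#' Given a pairwise alignment as a paired index map, maps the reference P1
#' position onto the query and reports P1 and P1' (= P1 + 1) with their
#' residue identities. The alignment itself is an input (e.g. from
#' [align_pair()] or an external aligner); the operation is pure index
#' bookkeeping.
#'
#' @param query,reference [serpin_sequence] objects.
#' @param reference_p1 P1 index on the reference (1-based).
#' @param alignment Data frame with columns `ref` and `query`: one row per
#'   alignment column, residue indices or NA at gaps.
#' @return A list with `P1`, `P1prime` (query indices), `P1_residue`,
#'   `P1prime_residue`, and the aligned reference residue.
#' @export
transfer_p1 <- function(query, reference, reference_p1, alignment) {
  stopifnot(inherits(query, "serpin_sequence"),
            inherits(reference, "serpin_sequence"),
            all(c("ref", "query") %in% names(alignment)))
  if (reference_p1 < 1L || reference_p1 > reference$length)
    stop("reference_p1 out of range")
  row <- which(!is.na(alignment$ref) & alignment$ref == reference_p1)
  if (length(row) != 1L)
    stop("alignment does not map reference position ", reference_p1,
         " exactly once")
  p1 <- alignment$query[row]
  if (is.na(p1))
    stop("unmapped P1: reference position ", reference_p1,
         " is aligned to a gap in the query")
  if (p1 + 1L > query$length)
    stop("P1' (", p1 + 1L, ") exceeds the query length")
  list(P1 = p1, P1prime = p1 + 1L,
       P1_residue = substr(query$residues, p1, p1),
       P1prime_residue = substr(query$residues, p1 + 1L, p1 + 1L),
       reference_residue = substr(reference$residues, reference_p1,
                                  reference_p1))
}

#' Global pairwise alignment as a paired index map
#'
#' Convenience wrapper around `Biostrings::pairwiseAlignment()` (global,
#' BLOSUM62) producing the index-map format consumed by [transfer_p1()].
#'
#' @param query,reference [serpin_sequence] objects.
#' @return Data frame with columns `ref` and `query` (NA at gaps).
#' @export
align_pair <- function(query, reference) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("align_pair requires the Biostrings package")
  pa <- Biostrings::pairwiseAlignment(
    pattern = query$residues, subject = reference$residues,
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  qi <- cumsum(qa != "-"); ri <- cumsum(ra != "-")
  data.frame(ref = ifelse(ra == "-", NA_integer_, ri),
             query = ifelse(qa == "-", NA_integer_, qi))
}

#' Mass model for serpin moiety arithmetic
#'
#' @param mean_residue_kd Mean residue mass (kD per residue, default 0.110).
#' @param tag_kd Mass adjustment for purification tags (kD, default 0).
#' @param residue_masses Optional named vector of per-residue masses (kD)
#'   for sequence-exact tail masses; defaults to standard average residue
#'   masses when `exact = TRUE` is used downstream.
#' @return An object of class `mass_model`.
#' @export
mass_model <- function(mean_residue_kd = 0.110, tag_kd = 0,
                       residue_masses = NULL) {
  if (!is.finite(mean_residue_kd) || mean_residue_kd <= 0)
    stop("mean residue mass must be > 0")
  if (!is.null(residue_masses) && any(residue_masses <= 0))
    stop("per-residue masses must be > 0")
  structure(list(mean_residue_kd = mean_residue_kd, tag_kd = tag_kd,
                 residue_masses = residue_masses),
            class = "mass_model")
}

#' Mass of the serpin moiety retained in the covalent complex
#'
#' Cleavage at P1 releases the C-terminal tail (residues P1'..length); the
#' N-terminal moiety of `p1` residues stays covalently bound to the
#' protease. Its mass is the full serpin mass minus the tail mass:
#' `(length - p1)` residues at the mean residue mass, or the sequence-exact
#' tail mass when a sequence is supplied.
#'
#' @param full_mass Full serpin mass (kD), > 0.
#' @param length Number of residues; `1 <= p1 < length`.
#' @param p1 P1 index (last residue retained in the complex).
#' @param model A [mass_model].
#' @param sequence Optional [serpin_sequence] for a sequence-exact tail
#'   mass (uses the model's residue table, or standard average masses).
#' @return Mass of the cleaved (complex-bound) moiety in kD.
#' @examples
#' cleaved_moiety_mass(44, 393, 357)  # 40.04
#' @export
cleaved_moiety_mass <- function(full_mass, length, p1, model = mass_model(),
                                sequence = NULL) {
  stopifnot(inherits(model, "mass_model"))
  if (!is.finite(full_mass) || full_mass <= 0)
    stop("full_mass must be > 0")
  if (p1 < 1L || p1 >= length)
    stop("p1 must satisfy 1 <= p1 < length (a zero-residue tail is not ",
         "a cleavage)")
  if (!is.null(sequence)) {
    stopifnot(inherits(sequence, "serpin_sequence"),
              sequence$length == length)
    tab <- if (is.null(model$residue_masses)) AA_RESIDUE_KD
           else model$residue_masses
    tail <- strsplit(substr(sequence$residues, p1 + 1L, length), "")[[1L]]
    tail_mass <- sum(tab[tail])
  } else {
    tail_mass <- (length - p1) * model$mean_residue_kd
  }
  full_mass - model$tag_kd - tail_mass
}

#' Predicted mass of the covalent serpin-protease complex
#'
#' The SDS-resistant complex carries the cleaved serpin moiety plus the
#' intact protease; its mass is their sum.
#'
#' @param serpin_cleaved Mass of the cleaved serpin moiety (kD), > 0.
#' @param protease Protease mass (kD), > 0.
#' @return Complex mass (kD).
#' @examples
#' predict_complex_mass(40, 36)  # ~76 kD
#' @export
predict_complex_mass <- function(serpin_cleaved, protease) {
  if (!is.finite(serpin_cleaved) || serpin_cleaved <= 0)
    stop("serpin moiety mass must be > 0")
  if (!is.finite(protease) || protease <= 0)
    stop("protease mass must be > 0")
  serpin_cleaved + protease
}
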