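# FG-motif valence accounting for fusion-protein constructs: motif
# counting, F->A / FG->AA mutation application, and residue-composition
# fractions. Coordinates are 1-based inclusive, matching protein
# literature convention.

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Protein sequence with region annotations
#'
#' @param id sequence identifier.
#' @param residues one-letter amino-acid string (case-insensitive; stored
#'   upper case).
#' @param regions named list of `c(start, end)` 1-based inclusive
#'   intervals.
#' @return object of class `protein_sequence`.
#' @export
protein_sequence <- function(id, residues, regions = list()) {
  residues <- toupper(residues)
  chars <- strsplit(residues, "")[[1]]
  if (length(chars) > 0 && !all(chars %in% .aa_alphabet)) {
    stop("residues outside the 20-letter amino-acid alphabet")
  }
  n <- nchar(residues)
  for (nm in names(regions)) {
    r <- regions[[nm]]
    if (length(r) != 2 || r[1] < 1 || r[2] > n || r[1] > r[2]) {
      stop("region '", nm, "' out of bounds")
    }
  }
  structure(list(id = id, residues = residues, regions = regions),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s (%d aa, %d region(s))\n",
              x$id, nchar(x$residues), length(x$regions)))
  invisible(x)
}

resolve_region <- function(seq, region) {
  n <- nchar(seq$residues)
  if (is.null(region)) return(c(1L, n))
  if (is.character(region)) {
    if (!region %in% names(seq$regions)) stop("unknown region: ", region)
    region <- seq$regions[[region]]
  }
  region <- as.integer(region)
  if (region[1] < 1 || region[2] > n || region[1] > region[2]) {
    stop("region out of sequence bounds")
  }
  region
}

count_motif <- function(seq, motif, region) {
  if (nchar(seq$residues) == 0) {
    warning("empty sequence")
    return(0L)
  }
  r <- resolve_region(seq, region)
  s <- substr(seq$residues, r[1], r[2])
  # lookahead so overlapping occurrences (possible for GLFG) all count
  m <- gregexpr(paste0("(?=", motif, ")"), s, perl = TRUE)[[1]]
  if (m[1] == -1) 0L else length(m)
}

#' Count FG-motif valence
#'
#' Number of FG dipeptides in the sequence (or a region). Every GLFG
#' contains exactly one FG, so GLFG motifs are counted once here — total
#' FG valence in the field's sense.
#'
#' @param seq a [protein_sequence].
#' @param region `NULL` (whole sequence), a region name, or
#'   `c(start, end)` 1-based inclusive.
#' @return integer count.
#' @export
count_fg <- function(seq, region = NULL) {
  count_motif(seq, "FG", region)
}

#' Count GLFG tetrapeptide motifs
#'
#' @inheritParams count_fg
#' @return integer count; always `<=` [count_fg()] on the same region.
#' @export
count_glfg <- function(seq, region = NULL) {
  count_motif(seq, "GLFG", region)
}

#' Apply F->A / FG->AA mutations to a sequence
#'
#' Each row of the spec targets the F of one motif: kind `"F>A"`
#' replaces that single phenylalanine with alanine; `"FG>AA"` replaces
#' the F and the following G with two alanines. Positions that do not
#' hold the expected residues are a validation error naming the
#' position. Sequence length is unchanged.
#'
#' @param seq a [protein_sequence].
#' @param spec data.frame with columns `position` (1-based index of the
#'   F) and `kind` (`"F>A"` or `"FG>AA"`); zero rows = identity.
#' @return the mutated [protein_sequence] (same regions).
#' @export
apply_mutations <- function(seq, spec) {
  stopifnot(inherits(seq, "protein_sequence"), is.data.frame(spec))
  if (nrow(spec) == 0) return(seq)
  stopifnot(all(c("position", "kind") %in% names(spec)))
  chars <- strsplit(seq$residues, "")[[1]]
  n <- length(chars)
  for (i in seq_len(nrow(spec))) {
    p <- spec$position[i]
    kind <- spec$kind[i]
    if (p < 1 || p > n) stop("mutation position ", p, " out of bounds")
    if (chars[p] != "F") {
      stop("position ", p, " holds '", chars[p], "', expected 'F'")
    }
    if (kind == "F>A") {
      chars[p] <- "A"
    } else if (kind == "FG>AA") {
      if (p + 1 > n || chars[p + 1] != "G") {
        stop("position ", p + 1, " does not hold the 'G' of an FG pair")
      }
      chars[p] <- "A"
      chars[p + 1] <- "A"
    } else {
      stop("unknown mutation kind: ", kind)
    }
  }
  protein_sequence(seq$id, paste(chars, collapse = ""), seq$regions)
}

#' Residue-composition fraction, whole-region or sliding-window
#'
#' @param seq a [protein_sequence].
#' @param residue_set character vector of one-letter residues (e.g.
#'   `c("N", "Q", "S", "T")`).
#' @param region as in [count_fg()].
#' @param window `NULL` for the whole-region fraction, or a window length
#'   for a stride-1 sliding profile.
#' @return a single fraction, or a numeric vector of per-window fractions
#'   (window start positions as names).
#' @export
composition_fraction <- function(seq, residue_set, region = NULL, window = NULL) {
  stopifnot(length(residue_set) >= 1)
  residue_set <- toupper(residue_set)
  r <- resolve_region(seq, region)
  chars <- strsplit(substr(seq$residues, r[1], r[2]), "")[[1]]
  hit <- chars %in% residue_set
  if (is.null(window)) return(mean(hit))
  n <- length(chars)
  if (window > n) stop("window longer than region")
  cs <- cumsum(c(0, hit))
  starts <- seq_len(n - window + 1)
  out <- (cs[starts + window] - cs[starts]) / window
  names(out) <- starts + r[1] - 1L
  out
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return named list of [protein_sequence] objects (no region
#'   annotations; add them after reading).
#' @export
read_fasta_sequences <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  out <- lapply(seq_along(aa), function(i) {
    protein_sequence(names(aa)[i], as.character(aa[[i]]))
  })
  names(out) <- names(aa)
  out
}

#' Write protein sequences to FASTA
#'
#' @param seqs list of [protein_sequence] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_sequences <- function(seqs, path) {
  if (inherits(seqs, "protein_sequence")) seqs <- list(seqs)
  aa <- Biostrings::AAStringSet(vapply(seqs, function(s) s$residues, character(1)))
  names(aa) <- vapply(seqs, function(s) s$id, character(1))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Build a mutation spec from generated-construct motif annotations
#'
#' Convenience for synthetic constructs from
#' [generate_construct_sequence()]: selects `n` motifs of a region (in
#' order of position) and returns the spec targeting each motif's F.
#'
#' @param seq a generated construct carrying the `motifs` attribute.
#' @param region region name (`"nterm"`/`"cterm"`).
#' @param kind `"F>A"` or `"FG>AA"`.
#' @param n number of motifs to target (default: all in the region).
#' @return data.frame spec for [apply_mutations()].
#' @export
mutation_spec_for_motifs <- function(seq, region, kind = c("FG>AA", "F>A"),
                                     n = NULL) {
  kind <- match.arg(kind)
  motifs <- attr(seq, "motifs")
  if (is.null(motifs)) stop("sequence carries no motif annotations")
  m <- motifs[motifs$region == region, , drop = FALSE]
  m <- m[order(m$f_pos), , drop = FALSE]
  if (is.null(n)) n <- nrow(m)
  if (n > nrow(m)) stop("fewer motifs in region than requested")
  m <- m[seq_len(n), , drop = FALSE]
  data.frame(position = m$f_pos, kind = kind, stringsAsFactors = FALSE)
}
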