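#' Recognition-site map
#'
#' Positions of a recognition motif on a sequence, 1-based, each the
#' position of the motif's first base on the forward strand.
#'
#' @param motif IUPAC motif string.
#' @param positions Strictly increasing 1-based start positions.
#' @param sequence_length Length of the scanned sequence (bp).
#' @return An object of class `site_map`.
#' @export
site_map <- function(motif, positions, sequence_length) {
  positions <- as.integer(positions)
  stopifnot(nchar(motif) >= 1, sequence_length >= nchar(motif),
            !is.unsorted(positions, strictly = TRUE) || !length(positions))
  if (length(positions) &&
      (min(positions) < 1L ||
       max(positions) > sequence_length - nchar(motif) + 1L)) {
    stop("site position outside [1, sequence_length - motif length + 1]",
         call. = FALSE)
  }
  structure(list(motif = motif, positions = positions,
                 sequence_length = as.integer(sequence_length)),
            class = "site_map")
}

#' @export
print.site_map <- function(x, ...) {
  cat(sprintf("%d site(s) of %s on a %d bp sequence\n",
              length(x$positions), x$motif, x$sequence_length))
  if (length(x$positions)) cat(" ", paste(x$positions, collapse = ", "), "\n")
  invisible(x)
}

valid_iupac <- function(chars) chars %in% names(Biostrings::IUPAC_CODE_MAP)

#' Find recognition sites of a motif on a DNA sequence
#'
#' IUPAC-aware scan for all occurrences of `motif`, reported as 1-based
#' forward-strand positions of the site's first base. Palindromic motifs
#' (equal to their reverse complement, as EcoRI's GAATTC or EcoRV's GATATC)
#' are searched on the forward strand only, which already equals the
#' double-stranded site set; non-palindromic motifs are additionally
#' searched on the reverse strand (as occurrences of the reverse-complement
#' pattern on the forward strand) and the union is reported.
#'
#' @param sequence A DNA sequence: character string or
#'   [Biostrings::DNAString]. Allowed characters: A, C, G, T, N.
#' @param motif IUPAC motif string.
#' @return A [site_map()].
#' @examples
#' find_sites("AAGAATTCAA", "GAATTC")$positions  # 3
#' @export
find_sites <- function(sequence, motif) {
  if (inherits(sequence, "DNAString")) {
    subject <- sequence
  } else {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    chars <- strsplit(toupper(sequence), "")[[1]]
    bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
    if (length(bad)) {
      stop(sprintf("invalid sequence character '%s' at position %d",
                   chars[bad[1]], bad[1]), call. = FALSE)
    }
    subject <- Biostrings::DNAString(paste(chars, collapse = ""))
  }
  motif <- toupper(motif)
  mchars <- strsplit(motif, "")[[1]]
  badm <- which(!valid_iupac(mchars))
  if (length(badm)) {
    stop(sprintf("invalid IUPAC code '%s' at motif position %d",
                 mchars[badm[1]], badm[1]), call. = FALSE)
  }
  pat <- Biostrings::DNAString(motif)
  hits <- Biostrings::start(
    Biostrings::matchPattern(pat, subject, fixed = FALSE))
  rc <- Biostrings::reverseComplement(pat)
  if (as.character(rc) != motif) {
    hits <- union(hits, Biostrings::start(
      Biostrings::matchPattern(rc, subject, fixed = FALSE)))
  }
  site_map(motif, sort(unique(hits)), length(subject))
}

#' Read a DNA sequence from a FASTA file
#'
#' @param path FASTA file path (multi-record allowed).
#' @param id Optional record identifier; by default the first record is
#'   used.
#' @return A character string (the sequence), named by its record id.
#' @export
read_fasta_sequence <- function(path, id = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  if (!length(set)) stop("no records in FASTA file: ", path, call. = FALSE)
  if (!is.null(id)) {
    hit <- which(sub("\\s.*$", "", names(set)) == id)
    if (!length(hit)) stop("record '", id, "' not found in ", path,
                           call. = FALSE)
    set <- set[hit[1]]
  } else {
    set <- set[1]
  }
  setNames(as.character(set), names(set))
}

#' Write a DNA sequence to a FASTA file
#'
#' @param sequence Character string.
#' @param path Output path.
#' @param name Record name. Default `"synthetic"`.
#' @return `path`, invisibly.
#' @export
write_fasta_sequence <- function(sequence, path, name = "synthetic") {
  set <- Biostrings::DNAStringSet(as.character(sequence))
  names(set) <- name
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a site map as a BED-like interval file
#'
#' Three required BED columns plus the motif as the name column: `chrom`,
#' 0-based `start`, exclusive `end`, `name`.
#'
#' @param sites A [site_map()].
#' @param path Output path.
#' @param chrom Chromosome/sequence name. Default `"tether"`.
#' @return `path`, invisibly.
#' @export
write_site_bed <- function(sites, path, chrom = "tether") {
  stopifnot(inherits(sites, "site_map"))
  m <- nchar(sites$motif)
  bed <- data.frame(chrom = chrom,
                    start = sites$positions - 1L,
                    end = sites$positions - 1L + m,
                    name = sites$motif)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
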