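#' Aligned DNA sequence sets
#'
#' A `dna_alignment` is a named character vector of equal-length,
#' upper-case aligned sequences over the DNA alphabet (ACGT), gaps
#' (`-`), `N`, `?`, `.` and the IUPAC ambiguity codes. Ambiguity codes
#' are legal here and are resolved by the distance functions' comparison
#' rules (they are treated as missing there), not at parse time.
#'
#' @param seqs Named character vector of aligned sequences.
#' @return A `dna_alignment`.
#' @examples
#' dna_alignment(c(a = "ACGT", b = "ACGA", c = "AC-A"))
#' @export
dna_alignment <- function(seqs) {
  if (!is.character(seqs) || length(seqs) < 2) {
    abort("an alignment needs at least 2 sequences")
  }
  ids <- names(seqs)
  if (is.null(ids) || any(ids == "") || anyNA(ids)) {
    abort("every sequence must be named by its specimen id")
  }
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicated specimen ids in alignment: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(seqs)
  len <- nchar(seqs)
  if (length(unique(len)) != 1L) {
    counts <- table(len)
    ref <- if (max(counts) > 1) {
      as.integer(names(counts)[which.max(counts)])
    } else {
      len[1]  # no majority: the first record sets the expectation
    }
    bad <- ids[len != ref][1]
    abort(sprintf(
      "sequences are not aligned: record '%s' has length %d, expected %d",
      bad, nchar(seqs[[bad]]), ref))
  }
  allowed <- c("A", "C", "G", "T", "U", "-", ".", "?", "N",
               "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
  chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  if (length(setdiff(chars, allowed))) {
    abort(sprintf("illegal residue character(s): %s",
                  paste(setdiff(chars, allowed), collapse = ", ")))
  }
  structure(seqs, class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("<dna_alignment: %d sequences of %d sites>\n",
              length(x), nchar(x[[1]])))
  show <- head(seq_along(x), 5)
  for (i in show) {
    s <- x[[i]]
    cat(sprintf("  %-12s %s%s\n", names(x)[i], substr(s, 1, 50),
                if (nchar(s) > 50) "..." else ""))
  }
  if (length(x) > 5) cat(sprintf("  ... %d more\n", length(x) - 5))
  invisible(x)
}

#' @method as_tibble dna_alignment
#' @export
as_tibble.dna_alignment <- function(x, ...) {
  tibble::tibble(specimen_id = names(x), sequence = unname(unclass(x)))
}

#' Read an aligned FASTA file
#'
#' Headers must be unique (the first whitespace-delimited token is the
#' specimen id) and all records the same length; a ragged record is an
#' error naming the offending id. Residues are upper-cased.
#'
#' @param path Path to a FASTA file.
#' @return A [dna_alignment()].
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- stats::setNames(as.character(set), ids)
  dna_alignment(seqs)
}

#' Write an alignment to FASTA
#'
#' Round-trips byte-exactly through [read_alignment()]: ids and residues
#' are preserved, one sequence line per record.
#'
#' @param aln A [dna_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "dna_alignment"))
  set <- Biostrings::BStringSet(unclass(aln))
  Biostrings::writeXStringSet(set, path, width = 20000L)
  invisible(path)
}

# internal: alignment as an n x L character matrix, rows named by id
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unclass(aln), ""))
  rownames(m) <- names(aln)
  m
}
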