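#' Load reference RNA sequences from FASTA
#'
#' Reads a FASTA file of reference RNA (or DNA-spelled) sequences into a
#' tibble, one row per record. Sequences are validated against the
#' `A/C/G/U/T/N` alphabet; `U` and `T` are treated as equivalent everywhere
#' base identity matters (background selection, lesion placement), and the
#' original spelling is retained for output.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A tibble of class `oab_reference` with columns `ref` (record id,
#'   first word of the header), `seq` (upper-case sequence, original
#'   U/T spelling) and `length` (nt).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "GAUC"), fa)
#' load_reference(fa)
#' @export
load_reference <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(fasta_path)
  if (length(set) == 0L) {
    stop("FASTA file contains no records: ", fasta_path, call. = FALSE)
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate reference id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  for (k in seq_along(seqs)) {
    if (nchar(seqs[k]) == 0L) {
      stop("empty sequence for record '", ids[k], "'", call. = FALSE)
    }
    bad <- regexpr("[^ACGUTN]", seqs[k])
    if (bad > 0L) {
      stop("illegal character '", substr(seqs[k], bad, bad),
           "' in record '", ids[k], "' at position ", bad, call. = FALSE)
    }
  }
  new_oab_reference(tibble(ref = unname(ids), seq = unname(seqs),
                           length = nchar(unname(seqs))))
}

new_oab_reference <- function(x) {
  class(x) <- c("oab_reference", class(x))
  x
}

#' Build a reference set from in-memory sequences
#'
#' Convenience constructor used in simulations and tests; applies the same
#' validation as [load_reference()].
#'
#' @param seqs Named character vector of sequences (names are reference ids).
#' @return An `oab_reference` tibble.
#' @export
reference_set <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  if (anyDuplicated(names(seqs))) stop("duplicate reference id(s)", call. = FALSE)
  seqs <- toupper(seqs)
  for (k in seq_along(seqs)) {
    if (nchar(seqs[k]) == 0L) stop("empty sequence for record '", names(seqs)[k], "'", call. = FALSE)
    bad <- regexpr("[^ACGUTN]", seqs[k])
    if (bad > 0L) {
      stop("illegal character '", substr(seqs[k], bad, bad), "' in record '",
           names(seqs)[k], "' at position ", bad, call. = FALSE)
    }
  }
  new_oab_reference(tibble(ref = names(seqs), seq = unname(seqs),
                           length = nchar(unname(seqs))))
}

# Per-position base vector for one reference, in RNA spelling (T -> U).
ref_bases <- function(ref, id) {
  row <- which(ref$ref == id)
  if (length(row) != 1L) stop("unknown reference id: ", id, call. = FALSE)
  chartr("T", "U", strsplit(ref$seq[row], "")[[1]])
}

# Long per-position table (ref, pos, base) across all references.
ref_position_table <- function(ref) {
  purrr::map_dfr(ref$ref, function(id) {
    b <- ref_bases(ref, id)
    tibble(ref = id, pos = seq_along(b), base = b)
  })
}
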