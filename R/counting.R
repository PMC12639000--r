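#' Count 5' read extremities per reference position
#'
#' Tallies, for every position of every reference, the number of retained
#' alignments whose (backshifted) 5' extremity falls there, together with a
#' coverage track and the total number of retained alignments. This is the
#' primary signal of aniline-cleavage sequencing: cleavage 3' of a fragile
#' nucleotide produces a 5'-phosphate fragment starting one nucleotide
#' downstream of the lesion, so a backshift of -1 places the signal on the
#' cleaved nucleotide itself.
#'
#' Retained alignments are primary, mapped, forward-strand records whose read
#' length is at least `min_read_len`, passing the multimapper filter:
#' secondary/supplementary records are always dropped; when an `NH` tag is
#' present, `NH > 1` records are dropped (if `exclude_multimapped`); otherwise
#' `MAPQ >= mapq_min` is required. The 5' extremity is the first *aligned*
#' base (leading soft clips ignored, as in the SAM `POS` convention).
#'
#' Coverage at position `i` is the number of retained reads whose aligned span
#' contains `i`, plus (for backshift -1) reads whose backshifted start is `i`
#' -- the cleaved nucleotide is not part of the fragment that reports it, and
#' adding those reads keeps the stop ratio at most 1 at fully cleaved
#' positions.
#'
#' @param alignments Path to a SAM or BAM file (need not be sorted).
#' @param ref An `oab_reference` from [load_reference()].
#' @param backshift Offset added to the 5' aligned position; `-1` (default)
#'   maps the signal onto the cleaved nucleotide, `0` reports raw read starts.
#'   Reads whose backshifted start falls before position 1 count towards
#'   `N_total` but not towards any position.
#' @param min_read_len Minimum read length in nt (default 8; shorter reads
#'   cannot be mapped unambiguously).
#' @param exclude_multimapped Drop reads with `NH > 1` when the tag is present
#'   (default `TRUE`).
#' @param mapq_min Minimum MAPQ required when no `NH` tag is available
#'   (default 1).
#' @return A tibble of class `oab_counts` with columns `ref`, `pos` (1-based),
#'   `base`, `n_start`, `coverage`, one row per reference position, and
#'   attributes `n_total` (named integer vector of retained alignments per
#'   reference) and `params`.
#' @export
count_five_prime_ends <- function(alignments, ref,
                                  backshift = -1L,
                                  min_read_len = 8L,
                                  exclude_multimapped = TRUE,
                                  mapq_min = 1L) {
  stopifnot(inherits(ref, "oab_reference"))
  backshift <- as.integer(backshift)
  if (!backshift %in% c(-1L, 0L)) stop("backshift must be -1 or 0", call. = FALSE)
  if (min_read_len < 1L) stop("min_read_len must be >= 1", call. = FALSE)

  aln <- read_alignment_records(alignments)

  unknown <- setdiff(unique(as.character(aln$rname)), ref$ref)
  unknown <- unknown[!is.na(unknown)]
  if (length(unknown) > 0L) {
    stop("alignment(s) to reference id(s) absent from the reference set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  keep <- !bitwAnd(aln$flag, 4L) &          # mapped
    !bitwAnd(aln$flag, 256L) &              # not secondary
    !bitwAnd(aln$flag, 2048L) &             # not supplementary
    !bitwAnd(aln$flag, 16L) &               # forward strand only
    aln$qwidth >= min_read_len
  n_reverse <- sum(!bitwAnd(aln$flag, 4L) & bitwAnd(aln$flag, 16L) > 0L)
  if (n_reverse > 0L) {
    message(n_reverse, " reverse-strand alignment(s) ignored")
  }
  has_nh <- !is.na(aln$NH)
  if (exclude_multimapped) {
    keep <- keep & ifelse(has_nh, aln$NH <= 1L, aln$mapq >= mapq_min)
  } else {
    keep <- keep & aln$mapq >= mapq_min
  }
  keep[is.na(keep)] <- FALSE
  aln <- aln[keep, , drop = FALSE]

  if (nrow(aln) == 0L) {
    warning("no alignments retained; returning empty counts", call. = FALSE)
  }

  out <- purrr::map_dfr(ref$ref, function(id) {
    b <- ref_bases(ref, id)
    L <- length(b)
    rows <- aln[!is.na(aln$rname) & aln$rname == id, , drop = FALSE]
    n <- integer(L)
    cov <- integer(L)
    if (nrow(rows) > 0L) {
      shifted <- rows$pos + backshift
      ok <- shifted >= 1L & shifted <= L
      n <- tabulate(shifted[ok], nbins = L)
      # span coverage via difference array over [pos, pos + rwidth - 1]
      lo <- pmax(rows$pos, 1L)
      hi <- pmin(rows$pos + rows$rwidth - 1L, L)
      valid <- lo <= hi
      d <- tabulate(lo[valid], nbins = L + 1L) - c(0L, tabulate(hi[valid], nbins = L))
      cov <- cumsum(d[seq_len(L)])
      if (backshift == -1L) cov <- cov + n
    }
    tibble(ref = id, pos = seq_len(L), base = b,
           n_start = as.integer(n), coverage = as.integer(cov))
  })

  n_total <- vapply(ref$ref, function(id) {
    sum(!is.na(aln$rname) & aln$rname == id)
  }, integer(1))

  new_oab_counts(out, n_total = n_total,
                 params = list(backshift = backshift, min_read_len = min_read_len,
                               exclude_multimapped = exclude_multimapped,
                               mapq_min = mapq_min))
}

new_oab_counts <- function(x, n_total, params) {
  attr(x, "n_total") <- n_total
  attr(x, "params") <- params
  class(x) <- unique(c("oab_counts", class(x)))
  x
}

#' Assemble a count table from vectors
#'
#' Constructor for in-memory count tables (simulation summaries, examples,
#' external counters); [count_five_prime_ends()] is the usual entry point.
#'
#' @param ref Reference id (scalar) or vector parallel to `bases`.
#' @param bases Per-position base characters.
#' @param n_start Per-position 5' start counts.
#' @param coverage Per-position coverage; defaults to `pmax(n_start, 1)`.
#' @param n_total Total retained alignments (default `sum(n_start)`).
#' @param backshift Backshift the counts were produced with (default -1).
#' @return An `oab_counts` tibble.
#' @export
five_prime_counts <- function(ref, bases, n_start, coverage = NULL,
                              n_total = NULL, backshift = -1L) {
  stopifnot(length(bases) == length(n_start), all(n_start >= 0))
  if (is.null(coverage)) coverage <- pmax(n_start, 1L)
  tbl <- tibble(ref = rep_len(ref, length(bases)), base = bases,
                n_start = as.integer(n_start),
                coverage = as.integer(coverage)) |>
    group_by(.data$ref) |>
    mutate(pos = dplyr::row_number()) |>
    ungroup() |>
    select("ref", "pos", "base", "n_start", "coverage")
  if (is.null(n_total)) {
    nt <- tapply(tbl$n_start, tbl$ref, sum)
    n_total <- setNames(as.integer(nt), names(nt))
  } else if (is.null(names(n_total))) {
    n_total <- setNames(as.integer(n_total), unique(tbl$ref))
  }
  new_oab_counts(tbl, n_total = n_total,
                 params = list(backshift = as.integer(backshift),
                               min_read_len = 8L,
                               exclude_multimapped = TRUE, mapq_min = 1L))
}

#' Total retained alignments per reference
#'
#' @param counts An `oab_counts` or `oab_scores` tibble.
#' @return Named integer vector of retained alignment counts per reference.
#' @export
n_total <- function(counts) attr(counts, "n_total")

# Read SAM/BAM into a plain data.frame of the fields the counter needs.
# SAM input is converted to BAM via Rsamtools (htslib) first.
read_alignment_records <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("flag", "rname", "pos", "mapq", "cigar", "qwidth"),
      tag = "NH"))[[1]]
  mapped <- !is.na(res$pos) & !is.na(res$cigar)
  rwidth <- rep(NA_integer_, length(res$pos))
  rwidth[mapped] <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar[mapped])
  nh <- res$tag$NH
  if (is.null(nh)) nh <- rep(NA_integer_, length(res$pos))
  data.frame(flag = res$flag, rname = as.character(res$rname), pos = res$pos,
             mapq = ifelse(is.na(res$mapq), 0L, res$mapq),
             qwidth = ifelse(is.na(res$qwidth), 0L, res$qwidth),
             rwidth = rwidth, NH = nh, stringsAsFactors = FALSE)
}

#' Write / read a 5' end count table
#'
#' The TSV carries one row per reference position with columns
#' `ref, pos, base, n_start, coverage`; per-reference alignment totals and the
#' counting parameters are stored in `#`-prefixed header lines so that
#' [read_counts()] is a lossless round trip.
#'
#' @param counts An `oab_counts` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "oab_counts"))
  nt <- n_total(counts)
  p <- attr(counts, "params")
  hdr <- c(
    paste0("# oabseq counts v1"),
    paste0("# params backshift=", p$backshift, " min_read_len=", p$min_read_len,
           " exclude_multimapped=", p$exclude_multimapped, " mapq_min=", p$mapq_min),
    paste0("# n_total ", names(nt), " ", as.integer(nt))
  )
  writeLines(hdr, path)
  readr::write_tsv(as_tibble(counts)[, c("ref", "pos", "base", "n_start", "coverage")],
                   path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  nt_lines <- hdr[grepl("^# n_total ", hdr)]
  nt <- integer(0)
  if (length(nt_lines) > 0L) {
    parts <- strsplit(sub("^# n_total ", "", nt_lines), " ")
    nt <- setNames(as.integer(vapply(parts, `[`, character(1), 2L)),
                   vapply(parts, `[`, character(1), 1L))
  }
  params <- list(backshift = -1L, min_read_len = 8L,
                 exclude_multimapped = TRUE, mapq_min = 1L)
  pl <- hdr[grepl("^# params ", hdr)]
  if (length(pl) == 1L) {
    kv <- strsplit(strsplit(sub("^# params ", "", pl), " ")[[1]], "=")
    vals <- setNames(vapply(kv, `[`, character(1), 2L),
                     vapply(kv, `[`, character(1), 1L))
    params <- list(backshift = as.integer(vals[["backshift"]]),
                   min_read_len = as.integer(vals[["min_read_len"]]),
                   exclude_multimapped = as.logical(vals[["exclude_multimapped"]]),
                   mapq_min = as.integer(vals[["mapq_min"]]))
  }
  tbl <- suppressWarnings(
    readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                    col_types = readr::cols(
                      ref = readr::col_character(),
                      pos = readr::col_integer(),
                      base = readr::col_character(),
                      n_start = readr::col_integer(),
                      coverage = readr::col_integer())))
  need <- c("ref", "pos", "base", "n_start", "coverage")
  if (!all(need %in% names(tbl))) {
    stop("malformed counts table: missing column(s) ",
         paste(setdiff(need, names(tbl)), collapse = ", "), call. = FALSE)
  }
  bad <- which(is.na(tbl$pos) | is.na(tbl$n_start) | is.na(tbl$coverage))
  if (length(bad) > 0L) {
    stop("malformed counts table at data line ", bad[1], call. = FALSE)
  }
  new_oab_counts(tbl, n_total = nt, params = params)
}

#' Export a per-position track as bedGraph
#'
#' Internal 1-based positions are converted to 0-based half-open single-base
#' spans; zero values are omitted, as is customary for sparse signal tracks.
#'
#' @param x An `oab_counts` or `oab_scores` tibble.
#' @param path Output bedGraph path.
#' @param column Column to export (default `"n_start"`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path, column = "n_start") {
  stopifnot(column %in% names(x))
  v <- x[[column]]
  keep <- !is.na(v) & v != 0
  df <- data.frame(chrom = x$ref[keep], start = x$pos[keep] - 1L,
                   end = x$pos[keep], value = v[keep])
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}
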