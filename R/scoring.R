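#' Per-position cleavage scores
#'
#' Computes the three per-position scores used to read out aniline-cleavage
#' signal, plus the random-error estimate, from a 5' end count table:
#'
#' * **stop ratio** -- reads starting at a position divided by reads
#'   overlapping it (`n_start / coverage`; missing where coverage is 0);
#' * **NCleavage** -- reads starting at a position times 1000 divided by the
#'   total number of reads aligned to the RNA;
#' * **NormGcounts (NGC)** -- reads starting at a position divided by the
#'   local background, defined as the median start count at non-G residues in
#'   an 11-nt window (+/- `window` nt), floored at `zero_background_floor`;
#' * **random error** -- `sqrt(n_start) / sqrt(background)`, with relative
#'   error `err / NGC = sqrt(background / n_start)` (missing where
#'   `n_start` is 0).
#'
#' NGC is computed at every position regardless of base identity; site
#' calling restricts by base downstream. The focal position is always
#' excluded from its own background so a strong signal cannot inflate it. If
#' a window holds fewer than `min_background_positions` non-G residues, the
#' reference-wide non-G median is used instead. `rel_err_poisson = 1/sqrt(n)`
#' is reported alongside as a conventional Poisson relative error; it is not
#' part of the published score and is labeled accordingly.
#'
#' @param counts An `oab_counts` tibble from [count_five_prime_ends()] or
#'   [read_counts()].
#' @param ref The matching `oab_reference` (only needed to re-derive bases
#'   when `counts` lacks them; normally `NULL`).
#' @param window Background window half-width in nt (default 5, i.e. an
#'   11-nt window).
#' @param min_background_positions Minimum non-G positions required in a
#'   window before falling back to the reference-wide background (default 3).
#' @param zero_background_floor Floor applied to the background median
#'   (default 1 count); prevents division by zero and caps NGC at `n_start`.
#' @param background_excluded_base Base excluded from the background
#'   (default `"G"`); `U`/`T` are equivalent in this test.
#' @return A tibble of class `oab_scores` with columns `ref, pos, base,
#'   n_start, coverage, stop_ratio, ncleavage, background, ngc, err,
#'   rel_err, rel_err_poisson, masked`, carrying `n_total` and scoring
#'   parameters as attributes.
#' @export
score_positions <- function(counts, ref = NULL, window = 5L,
                            min_background_positions = 3L,
                            zero_background_floor = 1,
                            background_excluded_base = "G") {
  stopifnot(inherits(counts, "oab_counts"))
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  if (zero_background_floor < 1) stop("zero_background_floor must be >= 1", call. = FALSE)
  x <- as_tibble(counts)
  x <- stop_ratio(x)
  x <- ncleavage(x, n_total = n_total(counts))
  x <- norm_g_counts(x, window = window,
                     min_background_positions = min_background_positions,
                     zero_background_floor = zero_background_floor,
                     background_excluded_base = background_excluded_base)
  x <- random_error(x)
  x$masked <- FALSE
  new_oab_scores(x, n_total = n_total(counts),
                 params = list(window = window,
                               min_background_positions = min_background_positions,
                               zero_background_floor = zero_background_floor,
                               background_excluded_base = background_excluded_base,
                               counting = attr(counts, "params")))
}

new_oab_scores <- function(x, n_total, params) {
  attr(x, "n_total") <- n_total
  attr(x, "params") <- params
  class(x) <- unique(c("oab_scores", class(x)))
  x
}

#' @rdname score_positions
#' @param x A tibble with at least `n_start` and `coverage` columns.
#' @export
stop_ratio <- function(x) {
  mutate(x, stop_ratio = ifelse(.data$coverage > 0,
                                .data$n_start / .data$coverage, NA_real_))
}

#' @rdname score_positions
#' @param n_total Named vector of total aligned reads per reference; taken
#'   from the `oab_counts` attribute when `x` carries one.
#' @export
ncleavage <- function(x, n_total = NULL) {
  if (is.null(n_total)) n_total <- attr(x, "n_total")
  if (is.null(n_total)) stop("n_total is required", call. = FALSE)
  nt <- unname(n_total[x$ref])
  if (any(nt == 0, na.rm = TRUE)) {
    warning("reference(s) with zero aligned reads: NCleavage set to missing",
            call. = FALSE)
  }
  mutate(x, ncleavage = ifelse(!is.na(nt) & nt > 0,
                               1000 * .data$n_start / nt, NA_real_))
}

#' @rdname score_positions
#' @export
norm_g_counts <- function(x, window = 5L, min_background_positions = 3L,
                          zero_background_floor = 1,
                          background_excluded_base = "G") {
  stopifnot(all(c("ref", "pos", "base", "n_start") %in% names(x)))
  excluded <- toupper(background_excluded_base)
  res <- x |>
    group_by(.data$ref) |>
    dplyr::group_modify(function(df, key) {
      df <- df[order(df$pos), , drop = FALSE]
      b <- chartr("T", "U", toupper(df$base))
      is_bg <- b != excluded
      if (!any(is_bg)) {
        stop("reference '", key$ref[1], "' has no non-", excluded,
             " positions: no background can be estimated; supply a mask or a ",
             "different background base", call. = FALSE)
      }
      n <- df$n_start
      L <- length(n)
      global_bg <- max(median(n[is_bg]), zero_background_floor)
      B <- vapply(seq_len(L), function(i) {
        j <- max(1L, i - window):min(L, i + window)
        j <- j[j != i & is_bg[j]]
        if (length(j) < min_background_positions) return(global_bg)
        max(median(n[j]), zero_background_floor)
      }, numeric(1))
      df$background <- B
      df$ngc <- n / B
      df
    }) |>
    ungroup()
  res[match(paste(x$ref, x$pos), paste(res$ref, res$pos)), , drop = FALSE]
}

#' @rdname score_positions
#' @export
random_error <- function(x) {
  stopifnot(all(c("n_start", "background") %in% names(x)))
  mutate(x,
         err = sqrt(.data$n_start) / sqrt(.data$background),
         rel_err = ifelse(.data$n_start > 0,
                          sqrt(.data$background / .data$n_start), NA_real_),
         rel_err_poisson = ifelse(.data$n_start > 0,
                                  1 / sqrt(.data$n_start), NA_real_))
}

#' Mask known stoichiometric modifications
#'
#' Positions of documented natural modifications (such as m7G in rRNA) give
#' strong cleavage signals unrelated to oxidation and are excluded from site
#' calling and ranking. Masked rows remain in the table with `masked = TRUE`.
#'
#' @param scores An `oab_scores` tibble.
#' @param mask Either a BED file path, a `GRanges`, or a data frame with
#'   columns `ref`, `start`, `end` (0-based half-open, BED convention).
#' @return The scores tibble with `masked` updated; overlapping intervals are
#'   unioned.
#' @export
apply_mask <- function(scores, mask) {
  stopifnot(inherits(scores, "oab_scores"))
  if (is.null(mask)) return(scores)
  if (is.character(mask) && length(mask) == 1L) {
    gr <- rtracklayer::import(mask, format = "BED")
    mask <- tibble(ref = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,  # back to 0-based
                   end = GenomicRanges::end(gr))
  } else if (methods::is(mask, "GRanges")) {
    mask <- tibble(ref = as.character(GenomicRanges::seqnames(mask)),
                   start = GenomicRanges::start(mask) - 1L,
                   end = GenomicRanges::end(mask))
  }
  stopifnot(all(c("ref", "start", "end") %in% names(mask)))
  for (k in seq_len(nrow(mask))) {
    id <- mask$ref[k]
    if (!id %in% scores$ref) {
      warning("mask interval on unknown reference '", id, "' ignored", call. = FALSE)
      next
    }
    L <- max(scores$pos[scores$ref == id])
    lo <- mask$start[k] + 1L           # 1-based first masked position
    hi <- mask$end[k]
    if (lo < 1L || hi > L) {
      warning("mask interval [", mask$start[k], ",", mask$end[k],
              ") extends outside reference '", id, "'; clipped", call. = FALSE)
    }
    lo <- max(lo, 1L); hi <- min(hi, L)
    if (lo <= hi) {
      scores$masked <- scores$masked | (scores$ref == id &
                                          scores$pos >= lo & scores$pos <= hi)
    }
  }
  scores
}

#' Write a per-position score table as TSV
#'
#' @param scores An `oab_scores` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  readr::write_tsv(as_tibble(scores), path)
  invisible(path)
}
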