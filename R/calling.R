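#' Call oxidation sites with the three-criterion filter
#'
#' A position is a valid oxidation signal when it meets the NGC threshold
#' (`ngc >= ngc_threshold`), exhibits coverage exceeding `min_coverage`
#' (strict `>`), and its relative random error is below `max_rel_error`
#' (strict `<`). Calling is optionally restricted to one base (G by default:
#' guanosine is by far the most easily oxidized nucleobase and carries the
#' bulk of the signal); masked positions never pass. All positions are
#' retained in the output together with the reasons they failed.
#'
#' @param scores An `oab_scores` tibble (mask already applied if desired).
#' @param ngc_threshold NGC threshold (default 10, i.e. ten times the
#'   background median).
#' @param min_coverage Coverage must strictly exceed this (default 1000).
#' @param max_rel_error Relative random error must be strictly below this
#'   (default 0.10).
#' @param restrict_to_base Only this base may pass (default `"G"`; `NULL`
#'   disables the restriction). `U`/`T` equivalent.
#' @return A tibble of class `oab_calls` with columns `ref, pos, base, ngc,
#'   coverage, rel_err, masked, passed, fail_reasons` (comma-separated;
#'   empty iff passed); calling parameters stored as an attribute.
#' @export
call_sites <- function(scores, ngc_threshold = 10, min_coverage = 1000,
                       max_rel_error = 0.10, restrict_to_base = "G") {
  stopifnot(inherits(scores, "oab_scores"))
  stopifnot(ngc_threshold > 0, min_coverage >= 0,
            max_rel_error > 0, max_rel_error <= 1)
  b <- chartr("T", "U", toupper(scores$base))
  reasons <- purrr::pmap_chr(
    list(scores$ngc, scores$coverage, scores$rel_err, b, scores$masked),
    function(ngc, cov, re, base, masked) {
      r <- character(0)
      if (masked) r <- c(r, "masked")
      if (!is.null(restrict_to_base) &&
          base != chartr("T", "U", toupper(restrict_to_base))) r <- c(r, "base")
      if (is.na(ngc) || ngc < ngc_threshold) r <- c(r, "ngc_below_threshold")
      if (is.na(cov) || cov <= min_coverage) r <- c(r, "coverage")
      if (is.na(re) || re >= max_rel_error) r <- c(r, "rel_error")
      paste(r, collapse = ",")
    })
  out <- tibble(ref = scores$ref, pos = scores$pos, base = scores$base,
                ngc = scores$ngc, coverage = scores$coverage,
                rel_err = scores$rel_err, masked = scores$masked,
                passed = reasons == "", fail_reasons = reasons)
  attr(out, "params") <- list(ngc_threshold = ngc_threshold,
                              min_coverage = min_coverage,
                              max_rel_error = max_rel_error,
                              restrict_to_base = restrict_to_base)
  class(out) <- unique(c("oab_calls", class(out)))
  out
}

#' Noise level of a base class
#'
#' The noise level is the median NGC over unmasked positions of a base class;
#' positions at or above `noise_multiple` times it are flagged as clearly
#' above noise. The published displays use a three-fold multiple.
#'
#' @param scores An `oab_scores` tibble.
#' @param base Base class (default `"G"`; `U`/`T` equivalent).
#' @param noise_multiple Flagging multiple (default 3).
#' @return A list with `noise` (scalar median NGC; `NA` when the class is
#'   empty) and `flagged`, the unmasked positions of the class with an
#'   `above_noise` column.
#' @export
noise_level <- function(scores, base = "G", noise_multiple = 3) {
  stopifnot(inherits(scores, "oab_scores"))
  b <- chartr("T", "U", toupper(scores$base))
  sel <- b == chartr("T", "U", toupper(base)) & !scores$masked
  if (!any(sel)) {
    return(list(noise = NA_real_,
                flagged = tibble(ref = character(0), pos = integer(0),
                                 ngc = numeric(0), above_noise = logical(0))))
  }
  sub <- as_tibble(scores)[sel, c("ref", "pos", "ngc")]
  noise <- median(sub$ngc, na.rm = TRUE)
  sub$above_noise <- !is.na(sub$ngc) & sub$ngc >= noise_multiple * noise
  list(noise = noise, flagged = sub)
}

#' Compare two conditions or protocols
#'
#' Pairs per-position scores from two runs (for example alkaline
#' fragmentation vs Mg2+ fragmentation, or untreated vs oxidant-exposed) at
#' shared unmasked positions of the base of interest, and summarises
#' agreement as the squared Pearson correlation of log2 NGC over positions
#' where both runs exceed a display threshold. Points above the diagonal
#' (second condition stronger) are counted as a simple readout of signal
#' gain.
#'
#' @param a,b `oab_scores` tibbles on the same references.
#' @param ngc_display_threshold Rows enter the correlation only when both
#'   NGC values are at or above this (default 10).
#' @param restrict_to_base Base restriction (default `"G"`, `NULL` for all).
#' @return An object of class `oab_comparison`: list with `pairs` (all shared
#'   positions, columns `ngc_a`, `ngc_b`, `retained`), `r_squared`,
#'   `n_retained`, and `n_above_diagonal` (retained rows with
#'   `ngc_b > ngc_a`). Has [tidy()] and [glance()] methods.
#' @export
compare_conditions <- function(a, b, ngc_display_threshold = 10,
                               restrict_to_base = "G") {
  stopifnot(inherits(a, "oab_scores"), inherits(b, "oab_scores"))
  pa <- as_tibble(a)[, c("ref", "pos", "base", "ngc", "masked")]
  pb <- as_tibble(b)[, c("ref", "pos", "ngc", "masked")]
  pairs <- inner_join(pa, pb, by = c("ref", "pos"), suffix = c("_a", "_b"))
  pairs <- filter(pairs, !.data$masked_a, !.data$masked_b)
  if (!is.null(restrict_to_base)) {
    pairs <- filter(pairs, chartr("T", "U", toupper(.data$base)) ==
                      chartr("T", "U", toupper(restrict_to_base)))
  }
  if (nrow(pairs) == 0L) {
    stop("no shared unmasked positions between the two score sets", call. = FALSE)
  }
  pairs <- pairs |>
    select("ref", "pos", "base", "ngc_a", "ngc_b") |>
    mutate(retained = !is.na(.data$ngc_a) & !is.na(.data$ngc_b) &
             .data$ngc_a >= ngc_display_threshold &
             .data$ngc_b >= ngc_display_threshold)
  ret <- pairs[pairs$retained, , drop = FALSE]
  r2 <- if (nrow(ret) >= 2 && sd(log2(ret$ngc_a)) > 0 && sd(log2(ret$ngc_b)) > 0) {
    stats::cor(log2(ret$ngc_a), log2(ret$ngc_b))^2
  } else if (nrow(ret) >= 2) 1 else NA_real_
  structure(list(pairs = pairs, r_squared = r2, n_retained = nrow(ret),
                 n_above_diagonal = sum(ret$ngc_b > ret$ngc_a),
                 ngc_display_threshold = ngc_display_threshold),
            class = "oab_comparison")
}

#' @export
tidy.oab_comparison <- function(x, ...) x$pairs

#' @export
glance.oab_comparison <- function(x, ...) {
  tibble(r_squared = x$r_squared, n_retained = x$n_retained,
         n_above_diagonal = x$n_above_diagonal,
         ngc_display_threshold = x$ngc_display_threshold)
}

#' @export
print.oab_comparison <- function(x, ...) {
  cat("Condition comparison:", nrow(x$pairs), "shared positions,",
      x$n_retained, "retained (both NGC >=", x$ngc_display_threshold, ")\n")
  cat(sprintf("  R^2 (log2 NGC) = %.4f; %d points above the diagonal\n",
              x$r_squared, x$n_above_diagonal))
  invisible(x)
}

#' Aggregate biological replicates
#'
#' Per-position mean and sample standard deviation of each score across
#' replicate runs. A single replicate reports SD 0 by convention and is
#' flagged by `n_rep`.
#'
#' @param replicates List of `oab_scores` tibbles over identical references.
#' @return A tibble with per-position `*_mean` and `*_sd` columns for each
#'   score and an `n_rep` column.
#' @export
aggregate_replicates <- function(replicates) {
  stopifnot(is.list(replicates), length(replicates) >= 1L)
  key0 <- paste(replicates[[1]]$ref, replicates[[1]]$pos)
  for (r in replicates[-1]) {
    if (!identical(paste(r$ref, r$pos), key0)) {
      stop("replicates cover different references/positions", call. = FALSE)
    }
  }
  score_cols <- intersect(c("stop_ratio", "ncleavage", "ngc"),
                          names(replicates[[1]]))
  long <- purrr::imap_dfr(replicates, function(r, i) {
    mutate(as_tibble(r)[, c("ref", "pos", "base", "masked", score_cols)],
           .rep = i)
  })
  long |>
    group_by(.data$ref, .data$pos, .data$base) |>
    summarise(across(dplyr::all_of(score_cols),
                     list(mean = ~mean(.x, na.rm = TRUE),
                          sd = ~ifelse(dplyr::n() > 1, sd(.x, na.rm = TRUE), 0))),
              masked = any(.data$masked),
              n_rep = dplyr::n(), .groups = "drop") |>
    arrange(.data$ref, .data$pos)
}

#' Rank the most severely damaged sites
#'
#' Orders unmasked positions by (mean) NGC, descending, breaking ties by
#' reference id then position ascending, and returns the top `n` with log2
#' values for heatmap export.
#'
#' @param scores An `oab_scores` tibble or the output of
#'   [aggregate_replicates()] (its `ngc_mean` column is used).
#' @param n Number of sites to return (default 30).
#' @param restrict_to_base Base restriction (default `"G"`, `NULL` for all).
#' @return A tibble of the top sites with columns `ref, pos, base, ngc,
#'   log2_ngc, rank`.
#' @export
top_damaged_sites <- function(scores, n = 30, restrict_to_base = "G") {
  x <- as_tibble(scores)
  ngc_col <- if ("ngc" %in% names(x)) "ngc" else if ("ngc_mean" %in% names(x)) {
    "ngc_mean"
  } else stop("no NGC column found", call. = FALSE)
  if (!"masked" %in% names(x)) x$masked <- FALSE
  x <- filter(x, !.data$masked, !is.na(.data[[ngc_col]]))
  if (!is.null(restrict_to_base)) {
    x <- filter(x, chartr("T", "U", toupper(.data$base)) ==
                  chartr("T", "U", toupper(restrict_to_base)))
  }
  x <- arrange(x, dplyr::desc(.data[[ngc_col]]), .data$ref, .data$pos)
  if (n > nrow(x)) {
    warning("requested ", n, " sites but only ", nrow(x), " available", call. = FALSE)
    n <- nrow(x)
  }
  out <- x[seq_len(n), , drop = FALSE]
  tibble(ref = out$ref, pos = out$pos, base = out$base,
         ngc = out[[ngc_col]], log2_ngc = log2(out[[ngc_col]]),
         rank = seq_len(n))
}

#' Export called sites as BED
#'
#' Passed sites as 0-based half-open single-base intervals, with NGC in the
#' score column.
#'
#' @param calls An `oab_calls` tibble.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path) {
  stopifnot(inherits(calls, "oab_calls"))
  p <- calls[calls$passed, , drop = FALSE]
  df <- data.frame(chrom = p$ref, start = p$pos - 1L, end = p$pos,
                   name = paste0(p$base, p$pos), score = p$ngc,
                   strand = "+")
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}
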