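# Shared fixtures: tiny references, a hand-rolled SAM writer, and
# brute-force oracles kept deliberately independent of the package internals.

random_ref <- function(seed, L, id = "ref1", alphabet = c("A", "C", "G", "U")) {
  s <- withr::with_seed(seed, paste(sample(alphabet, L, TRUE), collapse = ""))
  reference_set(setNames(s, id))
}

# Minimal SAM emitter for constructed alignment tables. Columns: pos, len;
# optional flag, mapq, nh, rname.
write_test_sam <- function(records, ref, path = tempfile(fileext = ".sam")) {
  if (is.null(records$flag)) records$flag <- rep(0L, nrow(records))
  if (is.null(records$mapq)) records$mapq <- rep(30L, nrow(records))
  if (is.null(records$rname)) records$rname <- rep(ref$ref[1], nrow(records))
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", ref$ref, ref$length))
  seq_of <- setNames(chartr("U", "T", ref$seq), ref$ref)
  lines <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    sq <- substr(seq_of[[r$rname]], r$pos, r$pos + r$len - 1L)
    if (nchar(sq) < r$len) sq <- strrep("A", r$len)  # run off the end: pad
    tags <- if (!is.null(records$nh) && !is.na(r$nh)) sprintf("\tNH:i:%d", r$nh) else ""
    sprintf("read%04d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s%s",
            i, r$flag, r$rname, r$pos, r$mapq, r$len, sq,
            strrep("I", r$len), tags)
  }, character(1))
  writeLines(c(hdr, lines), path)
  path
}

# Naive per-record tally of 5' ends: the counting oracle. Loops record by
# record, re-deriving every filter from first principles.
brute_force_tally <- function(records, ref, backshift = -1L, min_read_len = 8L,
                              exclude_multimapped = TRUE, mapq_min = 1L) {
  if (is.null(records$flag)) records$flag <- rep(0L, nrow(records))
  if (is.null(records$mapq)) records$mapq <- rep(30L, nrow(records))
  if (is.null(records$rname)) records$rname <- rep(ref$ref[1], nrow(records))
  out <- lapply(setNames(ref$ref, ref$ref), function(id) {
    integer(ref$length[ref$ref == id])
  })
  n_total <- setNames(integer(length(ref$ref)), ref$ref)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (bitwAnd(r$flag, 4L) || bitwAnd(r$flag, 16L) ||
        bitwAnd(r$flag, 256L) || bitwAnd(r$flag, 2048L)) next
    if (r$len < min_read_len) next
    nh <- if (!is.null(records$nh)) r$nh else NA
    if (!is.na(nh)) {
      if (exclude_multimapped && nh > 1L) next
      if (!exclude_multimapped && r$mapq < mapq_min) next
    } else if (r$mapq < mapq_min) next
    n_total[r$rname] <- n_total[r$rname] + 1L
    p <- r$pos + backshift
    if (p >= 1L && p <= length(out[[r$rname]])) {
      out[[r$rname]][p] <- out[[r$rname]][p] + 1L
    }
  }
  list(n = out, n_total = n_total)
}

# Brute-force windowed-median background: direct O(L*w) recomputation.
brute_force_background <- function(n, bases, w = 5L, min_bg = 3L, floor = 1) {
  bases <- chartr("T", "U", toupper(bases))
  is_bg <- bases != "G"
  L <- length(n)
  global_bg <- max(median(n[is_bg]), floor)
  vapply(seq_len(L), function(i) {
    j <- setdiff(max(1, i - w):min(L, i + w), i)
    j <- j[is_bg[j]]
    if (length(j) < min_bg) global_bg else max(median(n[j]), floor)
  }, numeric(1))
}

# Counts object built directly from vectors, for scoring tests that need no
# alignment file.
counts_from_vectors <- function(bases, n_start, coverage = NULL,
                                n_total = sum(n_start), id = "ref1",
                                backshift = -1L) {
  if (is.null(coverage)) coverage <- pmax(n_start, 1L)
  x <- tibble::tibble(ref = id, pos = seq_along(bases), base = bases,
                      n_start = as.integer(n_start),
                      coverage = as.integer(coverage))
  attr(x, "n_total") <- setNames(as.integer(n_total), id)
  attr(x, "params") <- list(backshift = backshift, min_read_len = 8L,
                            exclude_multimapped = TRUE, mapq_min = 1L)
  class(x) <- unique(c("oab_counts", class(x)))
  x
}

# Scores object assembled by hand, for site-calling tests.
scores_from_table <- function(df) {
  df <- tibble::as_tibble(df)
  if (is.null(df$masked)) df$masked <- FALSE
  attr(df, "n_total") <- setNames(1L, unique(df$ref)[1])
  attr(df, "params") <- list(window = 5L)
  class(df) <- unique(c("oab_scores", class(df)))
  df
}

# The acceptance-scale recovery scenario: 500-nt reference, 10 abasic
# lesions planted at well-separated interior G positions (lesions within a
# read length of the 3' terminus leave fragments too short to map and are
# chemically unobservable, so none are planted there).
recovery_scenario <- function(seed = 101L, L = 500L, n_lesions = 10L,
                              read_length = 50L) {
  ref <- random_ref(seed, L)
  b <- strsplit(ref$seq[1], "")[[1]]
  gpos <- which(b == "G")
  gpos <- gpos[gpos >= 20L & gpos <= L - read_length - 10L]
  les_pos <- gpos[round(seq(1, length(gpos), length.out = n_lesions))]
  lesions <- lesion_profile(ref, rep(ref$ref[1], n_lesions), les_pos,
                            rep("abasic", n_lesions))
  list(ref = ref, lesions = lesions, lesion_pos = les_pos)
}
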