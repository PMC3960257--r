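# Maximal repeat survey: forward (F), palindromic (P, reverse complement)
# and reverse (R, reversed but not complemented) orientations.

# Seed-and-extend enumeration of maximal repeated pairs.
#
# A pair of equal-length segments is maximal when the match cannot be
# extended by one base on either side. Seeds are exact k-mer matches
# (k = min_length, capped for long IR searches by the caller); every maximal
# pair of length >= k contains at least one seed, so extension + per-diagonal
# deduplication enumerates them all. Complexity is governed by the number of
# seed collisions, which is tiny for desk-scale plastomes.
maximal_pairs <- function(seq, orientation = c("F", "P", "R"), min_length) {
  orientation <- match.arg(orientation)
  n <- nchar(seq)
  empty <- tibble::tibble(pos1 = integer(), pos2 = integer(), length = integer())
  if (min_length > n) return(empty)
  k <- as.integer(min_length)

  x <- seq
  y <- switch(orientation, F = x, P = revcomp(x), R = rev_string(x))
  xv <- strsplit(x, "")[[1]]
  yv <- strsplit(y, "")[[1]]

  xk <- substring(x, 1:(n - k + 1L), k:n)
  xi <- split(seq_len(n - k + 1L), xk)
  if (orientation == "F") {
    yi <- xi
  } else {
    yk <- substring(y, 1:(n - k + 1L), k:n)
    yi <- split(seq_len(n - k + 1L), yk)
  }
  common <- intersect(names(xi), names(yi))
  if (length(common) == 0) return(empty)

  seeds_i <- integer(0); seeds_p <- integer(0)
  for (km in common) {
    ii <- xi[[km]]; pp <- yi[[km]]
    grid_i <- rep(ii, each = length(pp))
    grid_p <- rep(pp, times = length(ii))
    seeds_i <- c(seeds_i, grid_i)
    seeds_p <- c(seeds_p, grid_p)
  }
  if (orientation == "F") {
    keep <- seeds_i < seeds_p   # self-join symmetry; drop the trivial diagonal
    seeds_i <- seeds_i[keep]; seeds_p <- seeds_p[keep]
  }
  if (length(seeds_i) == 0) return(empty)

  # extend one seed per maximal run on each diagonal
  diag <- seeds_p - seeds_i
  ord <- order(diag, seeds_i)
  seeds_i <- seeds_i[ord]; seeds_p <- seeds_p[ord]; diag <- diag[ord]
  out_i <- integer(0); out_p <- integer(0); out_l <- integer(0)
  last_diag <- NA_integer_; run_end <- -1L
  for (s in seq_along(seeds_i)) {
    d <- diag[s]
    if (!is.na(last_diag) && d == last_diag && seeds_i[s] <= run_end) next
    i <- seeds_i[s]; p <- seeds_p[s]; l <- k
    while (i > 1L && p > 1L && xv[i - 1L] == yv[p - 1L]) { i <- i - 1L; p <- p - 1L; l <- l + 1L }
    while (i + l <= n && p + l <= n && xv[i + l] == yv[p + l]) l <- l + 1L
    out_i <- c(out_i, i); out_p <- c(out_p, p); out_l <- c(out_l, l)
    last_diag <- d; run_end <- i + l - 1L
  }

  if (orientation == "F") {
    res <- tibble::tibble(pos1 = out_i, pos2 = out_p, length = out_l)
  } else {
    # map the y-interval back onto x coordinates
    b_start <- n - out_p - out_l + 2L
    a_start <- out_i
    pos1 <- pmin(a_start, b_start)
    pos2 <- pmax(a_start, b_start)
    keep <- a_start != b_start      # drop identical intervals (self-palindromes)
    res <- tibble::tibble(pos1 = pos1, pos2 = pos2, length = out_l)[keep, ]
  }
  res <- dplyr::distinct(res)
  res[order(-res$length, res$pos1, res$pos2), ]
}

#' Expected count of repeated pairs under a uniform base model
#'
#' `E(l, n) = (n - l + 1) * (n - l) / 2 * 4^(-l)`: the expected number of
#' pairs of distinct length-`l` windows in a length-`n` i.i.d. uniform
#' sequence that match exactly, evaluated per orientation. This is the
#' package's own significance statistic for repeat filtering; it is
#' deliberately simple and documented rather than matching any external
#' tool's internal statistic.
#'
#' @param length Repeat length `l` in bp.
#' @param n Genome length in bp.
#' @return Expected pair count (numeric, vectorised over `length`).
#' @export
repeat_evalue <- function(length, n) {
  (n - length + 1) * (n - length) / 2 * 4^(-length)
}

#' Find maximal repeats in a plastome
#'
#' Enumerates all exact maximal repeated pairs in three orientations:
#' forward (`F`), palindromic (`P`, second copy reverse-complemented) and
#' reverse (`R`, second copy reversed but not complemented), then filters by
#' length and by the expectation statistic [repeat_evalue()]. A maximal pair
#' cannot be extended by one base at either end without breaking the match.
#'
#' The two inverted-repeat copies of a quadripartite plastome form one giant
#' palindromic hit; by default hits lying within that IR-vs-IR self match are
#' suppressed when a `partition` is supplied (set `include_ir_match = TRUE`
#' to keep them).
#'
#' @param genome A [plastome()] (or sequence string).
#' @param min_length Minimum repeat length in bp (default 20; must be >= 8).
#' @param max_e_value Keep hits with expectation value below this (default 1e-3).
#' @param annotation Optional [gene_models()] tibble for location classes.
#' @param partition Optional [region_partition()] used to suppress the
#'   IR self-match.
#' @param include_ir_match Keep palindromic hits inside the IR pair?
#' @return A tibble with columns `orientation`, `length`, `pos1`, `pos2`,
#'   `e_value`, `size_bin` and (with annotation) `location_class`, sorted by
#'   decreasing length then `pos1`.
#' @examples
#' sim <- make_plastome(1500, 300, 300, seed = 3)
#' find_maximal_repeats(sim$genome, min_length = 12, max_e_value = 10,
#'                      partition = sim$partition)
#' @export
find_maximal_repeats <- function(genome, min_length = 20, max_e_value = 1e-3,
                                 annotation = NULL, partition = NULL,
                                 include_ir_match = FALSE) {
  genome <- as_plastome(genome)
  if (min_length < 8) px_abort("min_length below 8 risks a combinatorial explosion", "bad_min_length")
  n <- plastome_length(genome)
  hits <- dplyr::bind_rows(lapply(c("F", "P", "R"), function(o) {
    h <- maximal_pairs(genome$seq, o, min_length)
    if (nrow(h)) h$orientation <- o
    h
  }))
  if (nrow(hits) == 0) {
    return(tibble::tibble(orientation = character(), length = integer(),
                          pos1 = integer(), pos2 = integer(), e_value = double(),
                          size_bin = character()))
  }
  hits$e_value <- repeat_evalue(hits$length, n)
  hits <- hits[hits$e_value <= max_e_value, , drop = FALSE]

  if (!include_ir_match && !is.null(partition)) {
    off <- partition$rotation_offset %||% 0L
    irb <- ((region_interval(partition, "IRb") - 1L + off) %% n) + 1L
    ira <- ((region_interval(partition, "IRa") - 1L + off) %% n) + 1L
    if (irb[1] <= irb[2] && ira[1] <= ira[2]) {
      inside_ir <- hits$orientation == "P" &
        hits$pos1 >= irb[1] & (hits$pos1 + hits$length - 1L) <= irb[2] &
        hits$pos2 >= ira[1] & (hits$pos2 + hits$length - 1L) <= ira[2]
      hits <- hits[!inside_ir, , drop = FALSE]
    }
  }

  hits$size_bin <- repeat_size_bin(hits$length)
  if (!is.null(annotation)) {
    hits$location_class <- classify_repeat_location(hits, annotation, n)
  }
  hits <- hits[order(-hits$length, hits$pos1, hits$pos2), ]
  tibble::as_tibble(hits[, c("orientation", "length", "pos1", "pos2", "e_value",
                             "size_bin",
                             intersect("location_class", names(hits)))])
}

repeat_size_bin <- function(length) {
  cut(length, breaks = c(-Inf, 24.5, 40.5, 80.5, Inf),
      labels = c("<25", "25-40", "41-80", ">80")) |> as.character()
}

# per-base annotation class vector: exon > intron > intergenic
location_class_vector <- function(annotation, genome_length) {
  cls <- rep("intergenic", genome_length)
  for (g in seq_len(nrow(annotation))) {
    ex <- annotation$exons[[g]]
    gaps <- exon_gaps(ex)
    for (j in seq_len(nrow(gaps))) {
      iv <- gaps[j, ]
      idx <- seq(iv$start, iv$end)
      cls[idx][cls[idx] == "intergenic"] <- "intron"
    }
  }
  for (g in seq_len(nrow(annotation))) {
    ex <- annotation$exons[[g]]
    for (j in seq_len(nrow(ex))) cls[seq(ex$start[j], ex$end[j])] <- "CDS"
  }
  cls
}

#' Classify repeat hits by genomic context
#'
#' Assigns each hit the class of its first copy: `CDS` (exonic, any gene
#' type), `intron`, or `intergenic`, by majority overlap of the copy-1
#' interval; ties resolve in that priority order.
#'
#' @param hits Tibble of repeat hits (needs `pos1`, `length`).
#' @param annotation A [gene_models()] tibble.
#' @param genome_length Genome length in bp.
#' @return Character vector of location classes, one per hit.
#' @export
classify_repeat_location <- function(hits, annotation, genome_length) {
  cls <- location_class_vector(annotation, genome_length)
  vapply(seq_len(nrow(hits)), function(i) {
    idx <- seq(hits$pos1[i], min(hits$pos1[i] + hits$length[i] - 1L, genome_length))
    tab <- table(factor(cls[idx], levels = c("CDS", "intron", "intergenic")))
    names(tab)[which.max(tab)]   # which.max breaks ties by priority order
  }, character(1))
}

#' Summarise repeat hits by orientation and size bin
#'
#' @param hits Tibble returned by [find_maximal_repeats()].
#' @return A tibble with the full orientation x size-bin crossing and count
#'   `n` (zero-filled); marginal totals are obtained by summing.
#' @export
summarize_repeats <- function(hits) {
  grid <- tidyr::expand_grid(orientation = c("F", "P", "R"),
                             size_bin = c("<25", "25-40", "41-80", ">80"))
  counted <- dplyr::count(hits, .data$orientation, .data$size_bin)
  out <- dplyr::left_join(grid, counted, by = c("orientation", "size_bin"))
  out$n[is.na(out$n)] <- 0L
  out
}
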