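#' Construct a plastome object
#'
#' A plastome is a (usually circular) chloroplast genome sequence. All
#' coordinates used throughout the package are 1-based inclusive positions on
#' this sequence.
#'
#' @param sequence Nucleotide string over `{A,C,G,T,N}`.
#' @param id Sequence identifier.
#' @param circular Is the molecule circular? Default `TRUE`.
#' @return An object of class `plastome`.
#' @examples
#' pg <- plastome("ACGTACGTACGT", id = "toy")
#' plastome_length(pg)
#' @export
plastome <- function(sequence, id = "plastome", circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) px_abort("plastome sequence is empty", "empty_sequence")
  check_alphabet(sequence, "plastome sequence")
  structure(
    list(id = id, seq = sequence, circular = isTRUE(circular)),
    class = "plastome"
  )
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf(
    "<plastome> %s: %s bp, %s\n", x$id, format(nchar(x$seq), big.mark = ","),
    if (x$circular) "circular" else "linear"
  ))
  invisible(x)
}

#' @rdname plastome
#' @param x A `plastome`.
#' @export
plastome_length <- function(x) nchar(x$seq)

as_plastome <- function(x) {
  if (inherits(x, "plastome")) return(x)
  if (is.character(x) && length(x) == 1L) return(plastome(x))
  px_abort("cannot interpret input as a plastome", "bad_input")
}

#' GC content of a plastome or sub-interval
#'
#' Fraction (G + C) / (A + C + G + T); N bases are excluded from the
#' denominator. With `start`/`end` omitted the whole genome is used.
#'
#' @param genome A [plastome()] (or bare sequence string).
#' @param start,end Optional 1-based inclusive interval bounds.
#' @return A fraction in `[0, 1]`.
#' @examples
#' gc_content(plastome("ACGT"))
#' @export
gc_content <- function(genome, start = NULL, end = NULL) {
  genome <- as_plastome(genome)
  n <- plastome_length(genome)
  start <- start %||% 1L
  end <- end %||% n
  if (start < 1L || end > n || start > end) {
    px_abort("interval outside genome bounds", "bad_interval")
  }
  seq <- substr(genome$seq, start, end)
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(seq), c("A", "C", "G", "T"))
  informative <- sum(counts)
  if (informative == 0) px_abort("interval has no informative (non-N) bases", "empty_interval")
  unname((counts[["C"]] + counts[["G"]]) / informative)
}

#' Construct a quadripartite region partition
#'
#' Describes the canonical plastome layout: large single-copy region (LSC),
#' inverted repeat B (IRb), small single-copy region (SSC) and inverted
#' repeat A (IRa), in that genomic order. Intervals are 1-based inclusive.
#' Either supply the four intervals, or just the three lengths to lay the
#' regions out canonically from position 1.
#'
#' @param lsc,irb,ssc,ira Length-2 integer vectors `c(start, end)`.
#' @param lsc_len,ssc_len,ir_len Alternative: region lengths; intervals are
#'   derived as LSC, IRb, SSC, IRa from position 1.
#' @param genome_id Optional identifier of the partitioned genome.
#' @return An object of class `region_partition`.
#' @examples
#' p <- region_partition(lsc_len = 79881, ssc_len = 12519, ir_len = 21481)
#' region_lengths_total(p)
#' @export
region_partition <- function(lsc = NULL, irb = NULL, ssc = NULL, ira = NULL,
                             lsc_len = NULL, ssc_len = NULL, ir_len = NULL,
                             genome_id = NA_character_) {
  if (!is.null(lsc_len)) {
    stopifnot(lsc_len > 0, ssc_len > 0, ir_len > 0)
    lsc <- c(1L, lsc_len)
    irb <- c(lsc_len + 1L, lsc_len + ir_len)
    ssc <- c(lsc_len + ir_len + 1L, lsc_len + ir_len + ssc_len)
    ira <- c(lsc_len + ir_len + ssc_len + 1L, lsc_len + 2L * ir_len + ssc_len)
  }
  regions <- tibble::tibble(
    region = c("LSC", "IRb", "SSC", "IRa"),
    start = as.integer(c(lsc[1], irb[1], ssc[1], ira[1])),
    end = as.integer(c(lsc[2], irb[2], ssc[2], ira[2]))
  )
  regions$length <- regions$end - regions$start + 1L
  if (any(regions$length <= 0)) px_abort("degenerate (empty) region in partition", "bad_partition")
  if (regions$length[regions$region == "IRa"] != regions$length[regions$region == "IRb"]) {
    px_abort("IRa and IRb lengths differ", "bad_partition")
  }
  structure(
    list(regions = regions, genome_id = genome_id,
         genome_length = sum(regions$length)),
    class = "region_partition"
  )
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("<region_partition> genome %s (%s bp)\n", x$genome_id,
              format(x$genome_length, big.mark = ",")))
  print(x$regions)
  invisible(x)
}

region_interval <- function(partition, region) {
  r <- partition$regions[partition$regions$region == region, ]
  c(r$start, r$end)
}

#' Total genome length implied by a region partition
#'
#' Sums LSC + SSC + 2 x IR, which must equal the genome length.
#'
#' @param partition A [region_partition()].
#' @return Integer total length in bp.
#' @examples
#' region_lengths_total(region_partition(lsc_len = 10, ssc_len = 5, ir_len = 10))
#' @export
region_lengths_total <- function(partition) {
  stopifnot(inherits(partition, "region_partition"))
  sum(partition$regions$length)
}

#' Detect the quadripartite structure of a plastome
#'
#' Finds the longest pair of disjoint, exactly reverse-complementary maximal
#' segments of length `>= min_ir_length` (the inverted repeats) and derives
#' the induced partition into LSC, IRb, SSC and IRa. The partition is
#' reported in canonical orientation: LSC is the longer single-copy region
#' and precedes IRb, which precedes SSC, which precedes IRa. When the input
#' coordinates do not already start at the LSC the genome is conceptually
#' rotated; the applied offset is stored as `rotation_offset` (positions map
#' back via `original = ((rotated - 1 + rotation_offset) %% n) + 1`).
#'
#' @param genome A [plastome()].
#' @param min_ir_length Minimum inverted-repeat length to consider (bp).
#' @return A [region_partition()] with a `rotation_offset` element.
#' @examples
#' sim <- make_plastome(2000, 400, 500, seed = 1)
#' detect_quadripartite(sim$genome, min_ir_length = 200)$regions
#' @export
detect_quadripartite <- function(genome, min_ir_length = 1000) {
  genome <- as_plastome(genome)
  n <- plastome_length(genome)
  if (n < 2L * min_ir_length) {
    px_abort("genome shorter than two inverted-repeat copies", "no_inverted_repeat")
  }
  hits <- maximal_pairs(genome$seq, orientation = "P",
                        min_length = min(31L, min_ir_length))
  if (nrow(hits) > 0) {
    # disjoint copies only, at the requested length
    hits <- hits[hits$length >= min_ir_length & hits$pos2 > hits$pos1 + hits$length - 1L, , drop = FALSE]
  }
  if (nrow(hits) == 0) {
    px_abort("no qualifying inverted-repeat pair found", "no_inverted_repeat")
  }
  best_len <- max(hits$length)
  best <- hits[hits$length == best_len, , drop = FALSE]
  if (nrow(best) > 1L) {
    px_abort("two non-nested inverted-repeat candidates tie in length",
             "ambiguous_structure")
  }
  s1 <- best$pos1; e1 <- s1 + best_len - 1L
  s2 <- best$pos2; e2 <- s2 + best_len - 1L

  # single-copy segments between the two IR copies (circular order)
  seg_mid_len <- s2 - e1 - 1L                 # between copy 1 and copy 2
  seg_wrap_len <- n - (e2 - s1 + 1L)          # wrapping through the origin
  if (seg_mid_len <= 0L || seg_wrap_len <= 0L) {
    px_abort("inverted-repeat copies leave no single-copy regions", "no_inverted_repeat")
  }
  if (seg_wrap_len >= seg_mid_len) {
    # LSC wraps the origin and ends just before copy 1, so copy 1 is IRb.
    # Rotate so the LSC starts at position 1.
    lsc_start <- (e2 %% n) + 1L
    offset <- lsc_start - 1L
    lsc_len <- seg_wrap_len; ssc_len <- seg_mid_len
  } else {
    lsc_start <- e1 + 1L
    offset <- lsc_start - 1L
    lsc_len <- seg_mid_len; ssc_len <- seg_wrap_len
  }
  part <- region_partition(lsc_len = lsc_len, ssc_len = ssc_len, ir_len = best_len,
                           genome_id = genome$id)
  part$rotation_offset <- offset %% n
  part
}

#' Extract a region's sequence given a partition
#'
#' @param genome A [plastome()].
#' @param partition A [region_partition()] for that genome.
#' @param region One of `"LSC"`, `"IRb"`, `"SSC"`, `"IRa"`.
#' @return Nucleotide string of the region (genome forward strand).
#' @export
region_sequence <- function(genome, partition, region) {
  genome <- as_plastome(genome)
  offset <- partition$rotation_offset %||% 0L
  iv <- region_interval(partition, region)
  n <- plastome_length(genome)
  start <- ((iv[1] - 1L + offset) %% n) + 1L
  circ_substr(genome$seq, start, iv[2] - iv[1] + 1L)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a region partition into one row per region
#'
#' @param x A [region_partition()].
#' @param ... Unused.
#' @return A tibble with columns `region`, `start`, `end`, `length`.
#' @export
tidy.region_partition <- function(x, ...) x$regions

#' One-row summary of a region partition
#'
#' @param x A [region_partition()].
#' @param ... Unused.
#' @return A one-row tibble with genome and region lengths.
#' @export
glance.region_partition <- function(x, ...) {
  r <- x$regions
  tibble::tibble(
    genome_id = x$genome_id,
    genome_length = x$genome_length,
    lsc_length = r$length[r$region == "LSC"],
    ssc_length = r$length[r$region == "SSC"],
    ir_length = r$length[r$region == "IRb"],
    rotation_offset = x$rotation_offset %||% 0L
  )
}
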