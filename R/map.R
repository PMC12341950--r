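#' Construct a genetic map
#'
#' A genetic map is the coordinate system of the whole pipeline: markers with
#' centimorgan (cM) positions on independent linkage groups (chromosomes),
#' each chromosome with a terminal position at or beyond its last marker.
#' Positions are continuous and 0-based at each chromosome start.
#'
#' @param markers data.frame with columns `marker`, `chromosome`,
#'   `position_cM`. Positions within a chromosome must be non-decreasing.
#' @param chrom_ends optional named numeric vector of terminal positions per
#'   chromosome (cM); defaults to each chromosome's last marker position.
#'
#' @return An object of class `genetic_map`: a list with elements `markers`
#'   (the validated data.frame) and `chrom_ends`.
#' @export
genetic_map <- function(markers, chrom_ends = NULL) {
  required <- c("marker", "chromosome", "position_cM")
  missing_cols <- setdiff(required, names(markers))
  if (length(missing_cols) > 0) {
    stop("genetic map is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  markers <- markers[, required]
  markers$marker <- as.character(markers$marker)
  markers$chromosome <- as.character(markers$chromosome)
  if (!is.numeric(markers$position_cM)) {
    stop("marker positions must be numeric (position_cM)")
  }
  if (anyNA(markers$position_cM)) {
    bad <- markers$marker[is.na(markers$position_cM)][1]
    stop("non-numeric or missing position for marker '", bad, "'")
  }
  if (any(markers$position_cM < 0)) {
    bad <- markers$marker[markers$position_cM < 0][1]
    stop("negative position for marker '", bad, "'")
  }
  dup <- markers$marker[duplicated(markers$marker)]
  if (length(dup) > 0) {
    stop("duplicate marker name(s): ", paste(unique(dup), collapse = ", "))
  }
  # chromosomes keep first-appearance order
  chroms <- unique(markers$chromosome)
  for (ch in chroms) {
    pos <- markers$position_cM[markers$chromosome == ch]
    if (length(pos) < 2) {
      stop("chromosome '", ch, "' has fewer than 2 markers")
    }
    if (is.unsorted(pos)) {
      idx <- which(markers$chromosome == ch)
      off <- idx[which(diff(pos) < 0)[1] + 1L]
      stop("marker positions not sorted on chromosome '", ch,
           "' at marker '", markers$marker[off], "'")
    }
  }
  last_pos <- vapply(chroms, function(ch) {
    max(markers$position_cM[markers$chromosome == ch])
  }, numeric(1))
  if (is.null(chrom_ends)) {
    chrom_ends <- last_pos
  } else {
    chrom_ends <- chrom_ends[chroms]
    if (anyNA(chrom_ends)) stop("chrom_ends must name every chromosome")
    if (any(chrom_ends < last_pos)) {
      bad <- chroms[which(chrom_ends < last_pos)[1]]
      stop("terminal position of chromosome '", bad,
           "' is before its last marker")
    }
    names(chrom_ends) <- chroms
  }
  rownames(markers) <- NULL
  structure(list(markers = markers, chrom_ends = chrom_ends),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("genetic_map:", nrow(x$markers), "markers on",
      length(x$chrom_ends), "chromosome(s)\n")
  ends <- paste0(names(x$chrom_ends), " (", format(x$chrom_ends), " cM)")
  cat(" ", paste(ends, collapse = ", "), "\n")
  invisible(x)
}

#' Chromosome names of a genetic map
#' @param map a `genetic_map`
#' @return character vector of chromosome ids in map order.
#' @export
map_chromosomes <- function(map) names(map$chrom_ends)

#' Total genetic length of a map
#' @param map a `genetic_map`
#' @return total length in cM (sum of chromosome terminal positions).
#' @export
map_length <- function(map) sum(map$chrom_ends)

#' Build an evenly spaced genetic map
#'
#' Markers are placed at 0, s, 2s, ... along each chromosome, plus a terminal
#' marker at the chromosome end when the grid does not land there. Marker
#' names are deterministic: `c{chr}m{idx}`.
#'
#' @param chromosome_lengths numeric vector of chromosome lengths (cM); names
#'   are used as chromosome ids (default `"1"`, `"2"`, ...).
#' @param marker_spacing grid spacing in cM.
#' @return a [genetic_map()].
#' @export
#' @examples
#' make_map(c(100, 70, 80, 80, 100), marker_spacing = 2)
make_map <- function(chromosome_lengths, marker_spacing) {
  if (any(chromosome_lengths <= 0)) stop("chromosome lengths must be > 0")
  if (marker_spacing <= 0) stop("marker_spacing must be > 0")
  if (any(marker_spacing > chromosome_lengths)) {
    stop("marker_spacing exceeds a chromosome length")
  }
  ids <- names(chromosome_lengths)
  if (is.null(ids)) ids <- as.character(seq_along(chromosome_lengths))
  rows <- lapply(seq_along(chromosome_lengths), function(i) {
    len <- chromosome_lengths[i]
    pos <- seq(0, len, by = marker_spacing)
    if (max(pos) < len) pos <- c(pos, len)
    data.frame(marker = sprintf("c%sm%d", ids[i], seq_along(pos)),
               chromosome = ids[i], position_cM = pos,
               stringsAsFactors = FALSE)
  })
  ends <- stats::setNames(as.numeric(chromosome_lengths), ids)
  genetic_map(do.call(rbind, rows), chrom_ends = ends)
}

#' Haldane map function
#'
#' Converts a genetic distance to a per-meiosis recombination fraction,
#' r = (1 - exp(-2d/100)) / 2.
#'
#' @param d distance in cM (vectorized).
#' @return recombination fraction in \[0, 0.5).
#' @export
haldane_r <- function(d) 0.5 * (1 - exp(-2 * d / 100))

#' Haldane-Waddington selfed-RIL recombination fraction
#'
#' For fully inbred selfed RILs the observed recombination fraction between
#' homozygous genotypes is R = 2r / (1 + 2r), the map-expansion of the
#' per-meiosis fraction r.
#'
#' @param r per-meiosis recombination fraction (e.g. from [haldane_r()]).
#' @return observed RIL recombination fraction in \[0, 0.5\].
#' @export
ril_recombination <- function(r) 2 * r / (1 + 2 * r)

# nearest marker (row index into map$markers) to a (chromosome, cM) locus
nearest_marker_index <- function(map, chromosome, pos_cM) {
  idx <- which(map$markers$chromosome == chromosome)
  if (length(idx) == 0) stop("no markers on chromosome '", chromosome, "'")
  d <- abs(map$markers$position_cM[idx] - pos_cM)
  idx[which.min(d)]
}
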