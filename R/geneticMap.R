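#' Build and validate a genetic map
#'
#' A genetic map is a plain data.frame with columns `marker`, `chrom`, `cM`
#' and `bp`, sorted by chromosome and position. Both genetic and physical
#' positions must be non-decreasing within a chromosome.
#'
#' @param marker character marker ids.
#' @param chrom chromosome ids (coerced to character).
#' @param cM genetic positions in centimorgans (>= 0).
#' @param bp physical positions in base pairs.
#' @return A validated `data.frame` with one row per marker.
#' @examples
#' makeGeneticMap(paste0("m", 1:3), rep("1H", 3), c(0, 10, 25),
#'                c(1e5, 2e6, 8e6))
#' @export
makeGeneticMap <- function(marker, chrom, cM, bp) {
  map <- data.frame(marker = as.character(marker),
                    chrom = as.character(chrom),
                    cM = as.numeric(cM), bp = as.numeric(bp),
                    stringsAsFactors = FALSE)
  validateGeneticMap(map)
}

validateGeneticMap <- function(map) {
  need <- c("marker", "chrom", "cM", "bp")
  if (!is.data.frame(map) || !all(need %in% colnames(map)))
    stop("genetic map needs columns marker, chrom, cM, bp")
  if (nrow(map) < 1L) stop("genetic map is empty")
  if (any(map$cM < 0)) stop("cM positions must be >= 0")
  if (anyDuplicated(map$marker)) stop("duplicated marker ids in map")
  ord <- order(map$chrom, map$cM, map$bp)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  for (ch in unique(map$chrom)) {
    sub <- map[map$chrom == ch, ]
    if (is.unsorted(sub$cM)) stop("cM not non-decreasing on chromosome ", ch)
    if (is.unsorted(sub$bp)) stop("bp not non-decreasing on chromosome ", ch)
  }
  map
}

#' Simulate a barley-like genetic map
#'
#' Markers are spread over `nChrom` chromosomes; genetic positions are drawn
#' uniformly over each chromosome's cM length and physical positions scale
#' the same order onto the chromosome's bp length (so cM and bp orders agree,
#' as on a consensus map).
#'
#' @param nMarkers total number of markers.
#' @param nChrom number of chromosomes (7 for barley).
#' @param chromLengthCM genetic length per chromosome (cM).
#' @param chromLengthBP physical length per chromosome (bp).
#' @param seed integer seed.
#' @return A genetic map data.frame (see [makeGeneticMap()]).
#' @export
simulateGeneticMap <- function(nMarkers, nChrom = 7L, chromLengthCM = 150,
                               chromLengthBP = 6e8, seed = 1L) {
  stopifnot(nMarkers >= nChrom)
  chromLengthCM <- rep_len(chromLengthCM, nChrom)
  chromLengthBP <- rep_len(chromLengthBP, nChrom)
  per <- rep(nMarkers %/% nChrom, nChrom)
  if (nMarkers %% nChrom > 0) per[seq_len(nMarkers %% nChrom)] <-
      per[seq_len(nMarkers %% nChrom)] + 1L
  withSeed(seed, {
    parts <- lapply(seq_len(nChrom), function(c) {
      cm <- sort(runif(per[c], 0, chromLengthCM[c]))
      # bp increases with cM but with jittered local spacing
      u <- sort(runif(per[c], 0, 1))
      data.frame(marker = sprintf("c%d_m%04d", c, seq_len(per[c])),
                 chrom = paste0(c, "H"), cM = cm,
                 bp = round(u * chromLengthBP[c]),
                 stringsAsFactors = FALSE)
    })
    validateGeneticMap(do.call(rbind, parts))
  })
}
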