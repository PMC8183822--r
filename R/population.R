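#' Simulate a MAGIC doubled-haploid population
#'
#' Executes the three crossing stages of the funnel design via
#' [simulateGamete()]. Each DH line descends from an independently simulated
#' funnel: gametes of two F1s form a four-way individual, gametes of two
#' founder-disjoint four-way individuals form the eight-way individual, and a
#' single gamete of that individual is doubled (DH), so every line is fully
#' homozygous and its mosaic records the founder of origin at every marker.
#' The expected genome share of each founder is 1/8.
#'
#' @param design a [FunnelDesign].
#' @param founders a [FounderPanel].
#' @param map genetic map aligned to the founder haplotypes.
#' @param seed integer seed; the population is bit-reproducible given it.
#' @return A [MagicPopulation] (markers x lines `SummarizedExperiment` with
#'   `dosage` and `mosaic` assays).
#' @export
simulateMagicPopulation <- function(design, founders, map, seed = 1L) {
  stopifnot(is(design, "FunnelDesign"), is(founders, "FounderPanel"))
  validObject(design); validObject(founders)
  map <- validateGeneticMap(map)
  H <- founders@haplotypes
  if (ncol(H) != nrow(map)) stop("founder haplotypes do not match map")
  p <- nrow(map)
  n <- sum(design@linesPerFunnel)
  dos <- matrix(0L, p, n)
  mos <- matrix(0L, p, n)
  funnel_of <- integer(n)

  withSeed(seed, {
    col <- 0L
    for (f in seq_len(nrow(design@stage3))) {
      setA <- design@stage2[design@stage3[f, 1], ]
      setB <- design@stage2[design@stage3[f, 2], ]
      for (l in seq_len(design@linesPerFunnel[f])) {
        col <- col + 1L
        fourA <- .crossF1s(setA[1], setA[2], design, H, map)
        fourB <- .crossF1s(setB[1], setB[2], design, H, map)
        gA <- simulateGamete(fourA$h1, fourA$h2, fourA$o1, fourA$o2, map)
        gB <- simulateGamete(fourB$h1, fourB$h2, fourB$o1, fourB$o2, map)
        dh <- simulateGamete(gA$hap, gB$hap, gA$origin, gB$origin, map)
        dos[, col] <- 2L * dh$hap
        mos[, col] <- dh$origin
        funnel_of[col] <- f
      }
    }
  })

  ids <- sprintf("MAGIC%03d", seq_len(n))
  colnames(dos) <- colnames(mos) <- ids
  rownames(dos) <- rownames(mos) <- map$marker
  se <- SummarizedExperiment(
    assays = list(dosage = dos, mosaic = mos),
    rowData = DataFrame(chrom = map$chrom, cM = map$cM, bp = map$bp,
                        row.names = map$marker),
    colData = DataFrame(line = ids, funnel = funnel_of, row.names = ids))
  out <- new("MagicPopulation", se)
  metadata(out)$seed <- as.integer(seed)
  metadata(out)$design <- design
  metadata(out)$founders <- founders
  validObject(out)
  out
}

# gamete of an F1 x gamete of another F1 -> a four-way individual
# (two haplotypes with founder-origin vectors)
.crossF1s <- function(i, j, design, H, map) {
  f1 <- function(k) {
    fo <- design@stage1[k, 1]; fm <- design@stage1[k, 2]
    simulateGamete(H[fo, ], H[fm, ], rep(fo, ncol(H)), rep(fm, ncol(H)), map)
  }
  ga <- f1(i); gb <- f1(j)
  list(h1 = ga$hap, h2 = gb$hap, o1 = ga$origin, o2 = gb$origin)
}

#' Extract the genetic map of a population
#'
#' @param pop a [MagicPopulation].
#' @return The genetic map data.frame.
#' @export
geneticMap <- function(pop) {
  rd <- rowData(pop)
  data.frame(marker = rownames(rd), chrom = rd$chrom, cM = rd$cM, bp = rd$bp,
             stringsAsFactors = FALSE)
}

#' Founder genome shares of a population
#'
#' @param pop a [MagicPopulation].
#' @return Numeric vector of length 8: fraction of all (line, marker) cells
#'   tracing to each founder.
#' @export
founderShares <- function(pop) {
  m <- founderMosaic(pop)
  tabulate(m, nbins = 8L) / length(m)
}

#' One-stop MAGIC simulation
#'
#' Convenience wrapper: builds a map, founders, funnel design and population
#' with the stated defaults (352 DH lines, 8 founders, 7 chromosomes).
#'
#' @param nLines number of DH lines.
#' @param nMarkers marker count on the simulated array.
#' @param seed master integer seed.
#' @param mafRange founder minor-allele-frequency interval.
#' @return A [MagicPopulation].
#' @export
simulateMagic <- function(nLines = 352L, nMarkers = 2000L, seed = 1L,
                          mafRange = c(0.1, 0.5)) {
  map <- simulateGeneticMap(nMarkers, seed = seed)
  fp <- simulateFounders(map, mafRange = mafRange, seed = seed + 1L)
  des <- buildFunnelDesign(fp, nLines, seed = seed + 2L)
  simulateMagicPopulation(des, fp, map, seed = seed + 3L)
}
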