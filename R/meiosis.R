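#' Simulate one gamete under the Haldane model
#'
#' Crossovers per chromosome are Poisson with mean equal to the map length in
#' Morgans and are placed uniformly on the cM scale (no interference), which
#' reproduces Haldane's map function: the recombination fraction between two
#' positions d Morgans apart is (1 - exp(-2d))/2. The founder-origin vector
#' switches parent exactly at crossover points.
#'
#' @param hap1,hap2 parental haplotype vectors (length p, aligned to `map`).
#' @param origin1,origin2 founder-origin vectors of the two parental
#'   haplotypes (same length; any integer labels).
#' @param map genetic map for the p markers.
#' @param seed optional integer seed; `NULL` uses the current RNG stream
#'   (callers that loop over many meioses seed once outside).
#' @return list with `hap` (alleles) and `origin` (founder labels).
#' @export
simulateGamete <- function(hap1, hap2, origin1, origin2, map, seed = NULL) {
  if (length(hap1) != nrow(map) || length(hap2) != nrow(map))
    stop("haplotype length does not match map")
  withSeed(seed, {
    pick <- integer(length(hap1)) # 0 -> haplotype 1, 1 -> haplotype 2
    for (ch in unique(map$chrom)) {
      i <- which(map$chrom == ch)
      cm <- map$cM[i]
      span <- max(cm) - min(cm)
      ncx <- rpois(1L, span / 100)
      start <- rbinom(1L, 1L, 0.5)
      if (ncx == 0L) {
        pick[i] <- start
      } else {
        xo <- sort(runif(ncx, min(cm), max(cm)))
        pick[i] <- (start + findInterval(cm, xo)) %% 2L
      }
    }
    sel <- pick == 1L
    hap <- ifelse(sel, hap2, hap1)
    origin <- ifelse(sel, origin2, origin1)
    list(hap = hap, origin = origin)
  })
}
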