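#' Build the eight-way MAGIC funnel design
#'
#' Stage 1 crosses each of the four old founders to one modern founder,
#' producing four F1s. Stage 2 performs the half-diallel among those F1s
#' (all 6 unordered pairs), each giving a four-way set that carries the
#' alleles of 4 of the 8 founders. Stage 3 unites pairs of founder-disjoint
#' four-way sets, so each eight-way funnel combines all 8 founders exactly
#' once; with 6 four-way sets there are 3 such disjoint pairings and all are
#' used. DH lines are distributed as evenly as possible across funnels, any
#' remainder going to the first funnels in a seeded random order.
#'
#' @param founders a [FounderPanel].
#' @param nLines total number of DH lines to derive (>= 1).
#' @param seed integer seed (used only to allocate remainder lines).
#' @return A [FunnelDesign].
#' @examples
#' fp <- simulateFounders(simulateGeneticMap(70, seed = 1), seed = 1)
#' buildFunnelDesign(fp, nLines = 352, seed = 1)
#' @export
buildFunnelDesign <- function(founders, nLines, seed = 1L) {
  stopifnot(is(founders, "FounderPanel"))
  validObject(founders)
  if (nLines < 1) stop("nLines must be >= 1: empty population rejected")
  old <- which(founders@group == "old")
  mod <- which(founders@group == "modern")
  if (length(old) != 4L || length(mod) != 4L)
    stop("founder panel without 4 old + 4 modern group structure")
  stage1 <- cbind(old = old, modern = mod)        # 4 F1s
  stage2 <- t(utils::combn(4L, 2L))               # 6 four-way sets (F1 pairs)
  colnames(stage2) <- c("f1a", "f1b")
  # disjoint pairings of F1 pairs: {12|34}, {13|24}, {14|23}
  pairings <- list(c(1L, 6L), c(2L, 5L), c(3L, 4L))
  idx <- which(vapply(pairings, function(pr)
    length(intersect(stage2[pr[1], ], stage2[pr[2], ])) == 0L, logical(1)))
  stage3 <- do.call(rbind, pairings[idx])
  colnames(stage3) <- c("setA", "setB")
  nf <- nrow(stage3)
  per <- rep(nLines %/% nf, nf)
  rem <- nLines %% nf
  withSeed(seed, {
    if (rem > 0) {
      ord <- sample.int(nf)
      per[ord[seq_len(rem)]] <- per[ord[seq_len(rem)]] + 1L
    }
  })
  new("FunnelDesign", stage1 = stage1, stage2 = stage2, stage3 = stage3,
      linesPerFunnel = as.integer(per), seed = as.integer(seed))
}
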