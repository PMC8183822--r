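#' Construct a founder panel
#'
#' @param haplotypes 8 x p binary matrix; row names are founder ids.
#' @param group length-8 character, `"old"` or `"modern"` (4 of each).
#' @param traits optional per-founder trait data.frame.
#' @return A [FounderPanel].
#' @export
founderPanel <- function(haplotypes, group, traits = data.frame()) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (is.null(rownames(haplotypes)))
    rownames(haplotypes) <- paste0("F", seq_len(nrow(haplotypes)))
  mono <- apply(haplotypes, 2, function(x) length(unique(x)) == 1L)
  new("FounderPanel", haplotypes = haplotypes, group = group,
      traits = traits, monomorphic = unname(mono))
}

#' Simulate eight founder haplotypes
#'
#' Draws a panel-wide minor-allele frequency per marker uniformly inside
#' `mafRange` and samples the eight founder alleles at that frequency.
#' Markers that end up monomorphic across the panel are flagged (not
#' removed); downstream QC drops them.
#'
#' @param map genetic map (defines the marker panel).
#' @param mafRange numeric length-2 interval inside (0, 0.5].
#' @param seed integer seed.
#' @return A [FounderPanel] with four "old" and four "modern" founders.
#' @export
simulateFounders <- function(map, mafRange = c(0.1, 0.5), seed = 1L) {
  map <- validateGeneticMap(map)
  if (length(mafRange) != 2L || mafRange[1] <= 0 || mafRange[2] > 0.5 ||
      mafRange[1] > mafRange[2])
    stop("mafRange must be an interval inside (0, 0.5]")
  p <- nrow(map)
  withSeed(seed, {
    maf <- runif(p, mafRange[1], mafRange[2])
    h <- matrix(0L, 8, p)
    for (k in seq_len(p)) {
      if (maf[k] >= 0.5 - 1e-12) {
        # forced MAF 0.5: exactly 4 copies of each allele
        h[sample.int(8, 4), k] <- 1L
      } else {
        h[, k] <- rbinom(8, 1, maf[k])
      }
    }
    colnames(h) <- map$marker
    rownames(h) <- c("Old1", "Old2", "Old3", "Old4",
                     "Mod1", "Mod2", "Mod3", "Mod4")
    # narrow days-to-heading spread among founders (winter 6-row types head
    # within ~4 days of each other)
    traits <- data.frame(founder = rownames(h),
                         DH = round(runif(8, 208, 212), 1),
                         GY = round(runif(8, 4.1, 7.3), 1))
    founderPanel(h, group = rep(c("old", "modern"), each = 4),
                 traits = traits)
  })
}
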