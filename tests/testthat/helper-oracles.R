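# brute-force mixed-model-equation solver used as an independent oracle:
# y = X beta + Zb b + Zg g + e, b ~ N(0, vb), g ~ N(0, vg), e ~ N(0, ve)
mmeBlups <- function(plots, vg, vb, ve, useDH = TRUE) {
  X <- if (useDH) model.matrix(~factor(rep) + DH, plots)
  else model.matrix(~factor(rep), plots)
  Zb <- model.matrix(~0 + factor(paste(rep, block, sep = ".")), plots)
  Zg <- model.matrix(~0 + factor(genotype), plots)
  W <- cbind(X, Zb, Zg)
  nb <- ncol(Zb); ng <- ncol(Zg); nf <- ncol(X)
  Dinv <- diag(c(rep(0, nf), rep(ve / max(vb, 1e-10), nb),
                 rep(ve / vg, ng)))
  sol <- solve(crossprod(W) + Dinv, crossprod(W, plots$GY))
  g <- sol[(nf + nb + 1):(nf + nb + ng)]
  names(g) <- levels(factor(plots$genotype))
  g - mean(g)
}

toyPlots <- function(n = 6, seed = 5, vg = 1, ve = 0.25) {
  set.seed(seed)
  g <- rnorm(n, 0, sqrt(vg))
  names(g) <- sprintf("G%02d", 1:n)
  dh <- setNames(rnorm(n, 210, 1), names(g))
  lay <- makeTrialLayout(names(g), env = "T", nReps = 2, blockSize = 3,
                         seed = seed)
  blk <- setNames(rnorm(length(unique(paste(lay$rep, lay$block))), 0, 0.4),
                  unique(paste(lay$rep, lay$block)))
  data.frame(env = "T", rep = lay$rep, block = lay$block,
             genotype = lay$genotype,
             DH = dh[lay$genotype],
             GY = 5 + g[lay$genotype] + blk[paste(lay$rep, lay$block)] -
               0.05 * (dh[lay$genotype] - 210) +
               rnorm(nrow(lay), 0, sqrt(ve)))
}

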