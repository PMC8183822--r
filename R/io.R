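#' Read a genotype table
#'
#' Tab-separated lines x markers dosage matrix (first column = line id), or
#' a minimal VCF restricted to biallelic SNPs with GT-only information:
#' homozygous calls map to dosage 0/2, heterozygous to 1, missing stays NA;
#' multi-allelic sites are skipped with a message.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"` (guessed from the extension by
#'   default).
#' @return lines x markers numeric matrix.
#' @export
readGenotypes <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (format == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                     check.names = FALSE, comment.char = "#")
    as.matrix(df)
  } else {
    .readMinimalVCF(path)
  }
}

.readMinimalVCF <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    multi <- grepl(",", vcfR::getALT(v))
    if (any(multi))
      message(sum(multi), " multi-allelic site(s) skipped")
    v <- v[!multi, ]
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, c(1, 2), .gtToDosage)
    rownames(dos) <- rownames(gt)
    return(t(dos))
  }
  # fallback parser for GT-only VCFs
  lines <- readLines(path)
  lines <- lines[!grepl("^##", lines)]
  hdr <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  if (length(hdr) < 10) stop("malformed VCF header")
  samples <- hdr[-(1:9)]
  body <- strsplit(lines[-1], "\t")
  skipped <- 0L
  rows <- list()
  ids <- character()
  for (fields in body) {
    if (grepl(",", fields[5])) { skipped <- skipped + 1L; next }
    gts <- sub(":.*", "", fields[-(1:9)])
    rows[[length(rows) + 1L]] <- vapply(gts, .gtToDosage, numeric(1))
    ids <- c(ids, if (fields[3] == ".")
      paste0(fields[1], "_", fields[2]) else fields[3])
  }
  if (skipped) message(skipped, " multi-allelic site(s) skipped")
  m <- do.call(rbind, rows)
  rownames(m) <- ids; colnames(m) <- samples
  t(m)
}

.gtToDosage <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_real_)
  al <- strsplit(gt, "[/|]")[[1]]
  if (any(al == ".")) return(NA_real_)
  sum(as.numeric(al))
}

#' Write a genotype table (TSV)
#'
#' @param X lines x markers dosage matrix (or [MagicPopulation]).
#' @param path output path.
#' @param comment optional header comment line(s), written with a leading
#'   `#`.
#' @export
writeGenotypes <- function(X, path, comment = NULL) {
  if (is(X, "MagicPopulation")) X <- markerMatrix(X)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  out <- data.frame(line = rownames(X), X, check.names = FALSE)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a minimal VCF for a DH population
#'
#' GT-only, biallelic sites; dosage 0 -> `0/0`, 2 -> `1/1` (1 -> `0/1`).
#'
#' @param pop a [MagicPopulation] (or lines x markers dosage matrix plus
#'   `map`).
#' @param path output path.
#' @param map genetic map (needed when `pop` is a plain matrix).
#' @export
writeVCF <- function(pop, path, map = NULL) {
  if (is(pop, "MagicPopulation")) {
    map <- geneticMap(pop)
    X <- markerMatrix(pop)
  } else X <- as.matrix(pop)
  if (is.null(map)) stop("a genetic map is required")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(X)),
                     collapse = "\t")), con)
  gt <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (k in seq_len(ncol(X))) {
    calls <- ifelse(is.na(X[, k]), "./.", gt[as.character(X[, k])])
    writeLines(paste(c(map$chrom[k], map$bp[k], map$marker[k], "A", "G",
                       ".", "PASS", ".", "GT", calls), collapse = "\t"),
               con)
  }
}

#' Read a plot table (CSV)
#'
#' Requires columns env, rep, block, genotype, DH, GY; duplicate plot keys
#' are rejected; missing GY cells are kept as NA (flagged, not dropped).
#'
#' @param path CSV path (comment lines starting with `#` are skipped).
#' @return Validated plot table data.frame.
#' @export
readPlotTable <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", comment.char = "#",
                   stringsAsFactors = FALSE)
  validatePlotTable(df)
}

#' Write a plot table (CSV)
#'
#' @param plots plot table.
#' @param path output path.
#' @param comment optional header comment.
#' @export
writePlotTable <- function(plots, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(plots, con, sep = ",", quote = FALSE, row.names = FALSE)
}

#' Read / write a genetic map (TSV: marker, chrom, cM, bp)
#'
#' @param path file path.
#' @return validated map data.frame.
#' @export
readGeneticMap <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  validateGeneticMap(df)
}

#' @rdname readGeneticMap
#' @param map map data.frame.
#' @param comment optional header comment.
#' @export
writeGeneticMap <- function(map, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(map, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a pipeline run configuration (YAML)
#'
#' @param path YAML file describing stages, sizes, seeds, MCMC profile
#'   (`test` or `production`) and
#'   the output directory; see [runPipeline()].
#' @return config list with defaults filled in.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  .fillConfig(cfg)
}

.fillConfig <- function(cfg) {
  defaults <- list(
    stages = c("simulate", "adjust", "fit", "optimize-tp", "crossval",
               "popgen"),
    nLines = 352L, nMarkers = 2000L, nEnvs = 9L, seed = 1L,
    mcmcProfile = "test", outDir = "magicGP-run",
    tpSize = 90L, nPartitions = 10L,
    seModels = c("GB", "BayesA"), meModels = c("MM", "MDs", "MDe"))
  cfg <- modifyList(defaults, cfg)
  cfg
}

#' Run the simulate -> adjust -> fit -> optimize -> crossvalidate pipeline
#'
#' Thin driver over the package's functions: simulates a MAGIC experiment
#' (or loads user files), computes adjusted means per environment, fits the
#' requested single- and multi-environment models, optimizes training
#' populations, cross-validates and writes CSV/JSON artifacts. Every output
#' file starts with a comment carrying the config hash and seed, and a rerun
#' with the same config is bit-identical.
#'
#' @param config a config list ([readRunConfig()]) or YAML path.
#' @param quiet suppress progress logging (stderr).
#' @return (invisibly) list of artifact paths, by stage.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- .fillConfig(config)
  if (!is.null(cfg$genotypes) && !file.exists(cfg$genotypes))
    stop("config genotype path does not exist: ", cfg$genotypes)
  hash <- .configHash(cfg)
  stamp <- sprintf("magicGP config=%s seed=%d", hash, as.integer(cfg$seed))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  log <- function(stage, ...) if (!quiet)
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                    paste0(...)))
  arts <- list()
  mcmc <- mcmcConfig(cfg$mcmcProfile, seed = cfg$seed)
  sim <- NULL; am <- NULL; mm <- NULL

  if ("simulate" %in% cfg$stages) {
    log("simulate", sprintf("n=%d p=%d", cfg$nLines, cfg$nMarkers))
    H2 <- c(0.660, 0.472, 0.532, 0.395, 0.652, 0.663, 0.122, 0.737, 0.805)
    ratio <- c(0.8, 0.8, 0.8, 1.2, 0.8, 0.8, 20, 1.0, 1.0)
    j <- seq_len(min(cfg$nEnvs, 9L))
    arch <- makeTraitArchitecture(cfg$nMarkers, envs = paste0("E", j),
                                  nQTL = 300L, gxeRatio = ratio[j],
                                  H2 = H2[j], seed = cfg$seed + 10L)
    sim <- simulateMagicExperiment(cfg$nLines, cfg$nMarkers, arch = arch,
                                   seed = cfg$seed)
    gp <- file.path(cfg$outDir, "genotypes.tsv")
    writeGenotypes(sim$pop, gp, comment = stamp)
    pp <- file.path(cfg$outDir, "plots.csv")
    writePlotTable(sim$plots, pp, comment = stamp)
    mp <- file.path(cfg$outDir, "map.tsv")
    writeGeneticMap(geneticMap(sim$pop), mp, comment = stamp)
    arts$simulate <- c(gp, pp, mp)
  }

  geno <- if (!is.null(sim)) markerMatrix(sim$pop)
    else readGenotypes(cfg$genotypes)
  plots <- if (!is.null(sim)) sim$plots else readPlotTable(cfg$plots)
  mm <- qcAndStandardize(geno)

  if ("adjust" %in% cfg$stages) {
    log("adjust", length(unique(plots$env)), " environments")
    am <- standardizePhenotypes(adjustedMeans(plots))
    ap <- file.path(cfg$outDir, "adjusted_means.csv")
    con <- file(ap, "w")
    writeLines(paste0("# ", stamp), con)
    write.table(data.frame(genotype = rownames(am@means), am@means,
                           check.names = FALSE),
                con, sep = ",", quote = FALSE, row.names = FALSE)
    close(con)
    vp <- file.path(cfg$outDir, "variance_report.json")
    jsonlite::write_json(list(config = hash, H2 = as.list(am@H2)), vp,
                         auto_unbox = TRUE, digits = NA)
    arts$adjust <- c(ap, vp)
  }

  if (any(c("fit", "crossval") %in% cfg$stages) && is.null(am))
    am <- standardizePhenotypes(adjustedMeans(plots))

  K <- grm(mm)
  if ("fit" %in% cfg$stages) {
    env1 <- colnames(am@means)[1]
    y <- am@means[rownames(mm@X), env1]
    log("fit", "SE models on ", env1, " + ME models")
    seFits <- list()
    for (mdl in cfg$seModels) {
      seFits[[mdl]] <- if (mdl %in% c("GB", "GK")) {
        Kk <- if (mdl == "GB") K else {
          D <- squaredEuclidean(mm)
          gaussianKernel(D, estimateBandwidth(D, y)$h)
        }
        fitSEKernel(Kk, y, mcmc)
      } else fitWGR(mm, y, wgrPriorConfig(mdl), mcmc)
    }
    data <- meDataset(am)
    meFits <- lapply(cfg$meModels, function(mdl) switch(mdl,
      MM = fitMM(data, K, mcmc), MDs = fitMDs(data, K, mcmc),
      MDe = fitMDe(data, K, mcmc = mcmc)))
    names(meFits) <- cfg$meModels
    fp <- file.path(cfg$outDir, "fit_summary.json")
    jsonlite::write_json(list(
      config = hash,
      se = lapply(seFits, function(f)
        if (is(f, "GPFit")) as.list(setNames(f@varComp$estimate,
                                             f@varComp$component))
        else list(varE = mean(f@chain[, "varE"]),
                  varG = mean(f@chain[, "varG"]))),
      me = lapply(meFits, function(f)
        as.list(setNames(f@varComp$estimate, f@varComp$component)))),
      fp, auto_unbox = TRUE, digits = NA)
    gp <- file.path(cfg$outDir, "gebv.csv")
    con <- file(gp, "w")
    writeLines(paste0("# ", stamp), con)
    write.table(data.frame(line = rownames(gebv(meFits[[1]])),
                           gebv(meFits[[1]]), check.names = FALSE),
                con, sep = ",", quote = FALSE, row.names = FALSE)
    close(con)
    arts$fit <- c(fp, gp)
  }

  if ("optimize-tp" %in% cfg$stages) {
    log("optimize-tp", "4 criteria, nSelect=", cfg$tpSize)
    ctx <- criterionContext(K)
    sels <- list(
      CDmean = exchangeOptimize("CDmean", ctx, cfg$tpSize,
                                seed = cfg$seed, lines = rownames(mm@X)),
      PEV = exchangeOptimize("PEV", ctx, cfg$tpSize, seed = cfg$seed,
                             lines = rownames(mm@X)),
      rScore = exchangeOptimize("rScore", ctx, cfg$tpSize,
                                seed = cfg$seed, lines = rownames(mm@X)),
      `E-NE` = entryToNearestEntrySelect(modifiedRogersDistance(mm),
                                         cfg$tpSize, seed = cfg$seed))
    tp <- file.path(cfg$outDir, "tp_selections.json")
    jsonlite::write_json(list(config = hash, selections = lapply(sels,
      function(s) list(criterion = s@criterion, value = s@value,
                       lines = s@selected, trajectory = s@trajectory))),
      tp, auto_unbox = TRUE, digits = NA)
    for (nm in names(sels)) {
      f <- file.path(cfg$outDir, paste0("tp_", gsub("[^A-Za-z]", "",
                                                    nm), ".txt"))
      writeLines(c(paste0("# ", stamp), sels[[nm]]@selected), f)
      arts$optimize <- c(arts$optimize, f)
    }
    arts$optimize <- c(arts$optimize, tp)
  }

  if ("crossval" %in% cfg$stages) {
    log("crossval", "CV1/CV2 x ", paste(cfg$meModels, collapse = ","))
    data <- meDataset(am)
    out <- list()
    for (scheme in c("CV1", "CV2")) {
      ps <- makeMEPartitions(data, scheme, nReps = cfg$nPartitions,
                             seed = cfg$seed)
      for (mdl in cfg$meModels) {
        cv <- runMECV(am@means, K, mdl, ps, mcmc)
        out[[paste(scheme, mdl, sep = "_")]] <-
          list(mean = cv@mean, sd = cv@sd, n = cv@nReps)
      }
    }
    cvp <- file.path(cfg$outDir, "cv_summary.json")
    jsonlite::write_json(c(list(config = hash), out), cvp,
                         auto_unbox = TRUE, digits = NA)
    arts$crossval <- cvp
  }

  if ("popgen" %in% cfg$stages) {
    log("popgen", "PCA + LD decay")
    pca <- runPCA(mm, 2)
    mapUse <- if (!is.null(sim)) geneticMap(sim$pop)
      else readGeneticMap(cfg$map)
    ld <- ldDecay(mm, mapUse)
    pp <- file.path(cfg$outDir, "pca.csv")
    con <- file(pp, "w")
    writeLines(paste0("# ", stamp), con)
    write.table(data.frame(line = rownames(pca$scores), pca$scores,
                           check.names = FALSE),
                con, sep = ",", quote = FALSE, row.names = FALSE)
    close(con)
    lp <- file.path(cfg$outDir, "ld_bins.csv")
    con <- file(lp, "w")
    writeLines(paste0("# ", stamp), con)
    write.table(ld$bins, con, sep = ",", quote = FALSE, row.names = FALSE)
    close(con)
    arts$popgen <- c(pp, lp)
  }
  invisible(arts)
}

.configHash <- function(cfg) {
  cfg <- cfg[setdiff(names(cfg), "outDir")] # where outputs land is not
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE) # identity
  # small rolling hash; enough to fingerprint a config in file headers
  v <- utf8ToInt(as.character(s))
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", h)
}
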