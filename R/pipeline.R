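# End-to-end orchestration: simulate (or load) -> diversity and
# differentiation -> clustering -> hybrid classification -> haplotype
# network -> phenology -> traits -> report bundle.

#' Build a pipeline run configuration
#'
#' @param simulation a [simulationConfig()] to generate inputs, or `NULL`
#'   to read them from files.
#' @param genepop,fasta,schedule,traits input paths (used when
#'   `simulation` is `NULL`).
#' @param outDir output directory.
#' @param Ks cluster numbers to scan.
#' @param reps replicate clustering runs per K.
#' @param burnin,sweeps MCMC lengths for both samplers.
#' @param connectionLimit parsimony network connection limit (steps).
#' @param bootReplicates bootstrap replicates for phenology intervals.
#' @param alpha significance level for Tukey letters.
#' @param c,h2 PST scaling constants.
#' @param callThreshold posterior threshold for hybrid calls.
#' @param excludeHybrids drop called hybrids before diversity, FST and
#'   trait group comparisons (the convention followed throughout).
#' @param phenologyPair the two schedule lineages contrasted in the
#'   phenology stage; default: the two most frequent labels.
#' @param seed global seed; all stage seeds derive from it.
#' @return a list of class `RunConfig`.
#' @export
runConfig <- function(simulation = simulationConfig(),
                      genepop = NULL, fasta = NULL, schedule = NULL,
                      traits = NULL, outDir = tempfile("cryptolin_run_"),
                      Ks = 1:4, reps = 3, burnin = 2000, sweeps = 8000,
                      connectionLimit = 7, bootReplicates = 1000,
                      alpha = 0.05, c = 1, h2 = 0.5,
                      callThreshold = 0.95, excludeHybrids = TRUE,
                      phenologyPair = NULL, seed = 1L) {
  cfg <- list(simulation = simulation, genepop = genepop, fasta = fasta,
              schedule = schedule, traits = traits, outDir = outDir,
              Ks = Ks, reps = reps, burnin = burnin, sweeps = sweeps,
              connectionLimit = connectionLimit,
              bootReplicates = bootReplicates, alpha = alpha, c = c,
              h2 = h2, callThreshold = callThreshold,
              excludeHybrids = excludeHybrids,
              phenologyPair = phenologyPair, seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  cfg
}

.stageSeed <- function(seed, k) (seed * 7919L + k * 104729L) %% 2147483647L

#' Run the full analysis pipeline
#'
#' Executes every stage on simulated or file inputs and writes a report
#' bundle (CSV tables per stage, `report.json`, `report.md`) into
#' `cfg$outDir`.  The run is idempotent under a fixed seed.  A stage
#' failure preserves the results written so far and stops with the stage
#' name.
#'
#' @param cfg a [runConfig()].
#' @return (invisibly) the report list.
#' @export
runPipeline <- function(cfg = runConfig()) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # ---- inputs --------------------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$simulation)) {
    sys <- stage("simulate", {
      s <- generateStudySystem(cfg$simulation,
                               seed = .stageSeed(cfg$seed, 1))
      writeStudySystem(s, file.path(cfg$outDir, "inputs"))
      s
    })
    g <- sys$genotypes; haplo <- sys$haplotypes
    sched <- sys$schedule; traitTab <- sys$traits; truth <- sys$truth
  } else {
    stage("load", {
      for (p in c(cfg$genepop, cfg$fasta, cfg$schedule, cfg$traits))
        if (!file.exists(p)) stop("input file not found: ", p)
    })
    g <- readGenepop(cfg$genepop)$genotypes
    haplo <- readHaplotypeFasta(cfg$fasta)
    sched <- readScheduleCsv(cfg$schedule)
    traitTab <- readTraitCsv(cfg$traits)
  }
  n <- nInd(g)

  # ---- clustering ----------------------------------------------------------
  clu <- stage("cluster", clusterKSeries(
    g, cfg$Ks, reps = cfg$reps, burnin = cfg$burnin, sweeps = cfg$sweeps,
    seed = .stageSeed(cfg$seed, 2)))
  dk <- if (length(cfg$Ks) >= 3 && cfg$reps >= 2)
    evannoDeltaK(clu$logLik) else NULL
  bestK <- if (!is.null(dk) && !is.na(selectK(dk)))
    selectK(dk) else max(cfg$Ks)
  best <- clu$results[[as.character(bestK)]][[1]]
  modal <- apply(posteriorMatrix(best), 1, which.max)
  cluster <- paste0("cluster", modal)
  utils::write.csv(
    data.frame(individual = individualNames(g), cluster = cluster,
               posteriorMatrix(best), check.names = FALSE),
    file.path(cfg$outDir, "cluster_posteriors.csv"), row.names = FALSE)
  if (!is.null(dk))
    utils::write.csv(dk, file.path(cfg$outDir, "deltaK.csv"),
                     row.names = FALSE)
  report$cluster <- list(bestK = bestK,
                         deltaK = if (is.null(dk)) NULL else dk$deltaK,
                         meanLogLik = rowMeans(clu$logLik))

  # ---- hybrid classification (pairwise over clusters) ---------------------
  hyb <- stage("hybrids", {
    lv <- sort(unique(cluster))
    callTab <- data.frame(individual = individualNames(g),
                          cluster = cluster, call = cluster,
                          stringsAsFactors = FALSE)
    pairRes <- list()
    if (length(lv) >= 2) {
      prs <- utils::combn(lv, 2)
      for (k in seq_len(ncol(prs))) {
        sel <- cluster %in% prs[, k]
        hp <- classifyHybrids(g[sel, ], burnin = cfg$burnin,
                              sweeps = cfg$sweeps,
                              seed = .stageSeed(cfg$seed, 10 + k))
        calls <- hybridCalls(hp, cfg$callThreshold)
        pairRes[[paste(prs[, k], collapse = ":")]] <- calls
        isHyb <- calls$call %in% c("F1", "F2", "BC_A", "BC_B")
        callTab$call[sel][isHyb] <- paste0("hybrid_",
                                           paste(prs[, k], collapse = ":"),
                                           "_", calls$call[isHyb])
      }
    }
    utils::write.csv(callTab, file.path(cfg$outDir, "hybrids.csv"),
                     row.names = FALSE)
    list(callTab = callTab, pairRes = pairRes)
  })
  isHybrid <- grepl("^hybrid_", hyb$callTab$call)
  report$hybrids <- list(nCalled = sum(isHybrid),
                         fraction = mean(isHybrid))

  # ---- diversity & differentiation (hybrids excluded) ---------------------
  keep <- if (cfg$excludeHybrids) !isHybrid else rep(TRUE, n)
  pg <- stage("popgen", {
    gp <- g[keep, ]
    grp <- cluster[keep]
    ds <- diversitySummary(gp, grp)
    fst <- wcFst(gp, grp)
    d2 <- genotypicDistanceMatrix(g)
    pc <- pcoa(d2, k = 2)
    utils::write.csv(ds, file.path(cfg$outDir, "diversity.csv"),
                     row.names = FALSE)
    utils::write.csv(fst$pairwise, file.path(cfg$outDir, "fst.csv"))
    utils::write.csv(
      data.frame(individual = rownames(pc$coordinates), pc$coordinates,
                 check.names = FALSE),
      file.path(cfg$outDir, "pcoa.csv"), row.names = FALSE)
    list(diversity = ds, fst = fst, pcoa = pc)
  })
  report$diversity <- pg$diversity
  report$fst <- list(theta = pg$fst$theta,
                     pairwise = pg$fst$pairwise)
  report$pcoa <- list(
    percentVariance = utils::head(pg$pcoa$percentVariance, 2))

  # ---- haplotype network ---------------------------------------------------
  net <- stage("network", {
    nw <- buildParsimonyNetwork(haplo, limit = cfg$connectionLimit)
    writeNetworkCsv(nw, file.path(cfg$outDir, "network_edges.csv"))
    writeNetworkGraphml(nw, file.path(cfg$outDir, "network.graphml"))
    nw
  })
  report$network <- list(
    nHaplotypes = sum(!networkNodes(net)$inferred),
    nComponents = length(unique(networkComponents(net))),
    frequencies = as.list(haplotypeFrequencies(haplo)))

  # ---- phenology -----------------------------------------------------------
  phen <- stage("phenology", {
    lin <- as.character(lineageLabels(sched))
    pair <- cfg$phenologyPair
    if (is.null(pair))
      pair <- names(sort(table(lin), decreasing = TRUE))[1:2]
    sel <- lin %in% pair
    s2 <- floweringSchedule(scheduleValues(sched)[sel, , drop = FALSE],
                            censusDates(sched), lin[sel])
    Ns <- table(factor(lin[sel], levels = pair))
    bootSeed <- .stageSeed(cfg$seed, 30)
    rows <- list()
    addCi <- function(label, statFn) {
      ci <- bootstrapCi(statFn, s2, replicates = cfg$bootReplicates,
                        seed = bootSeed + length(rows))
      for (i in seq_along(ci$estimate))
        rows[[length(rows) + 1]] <<- data.frame(
          statistic = if (length(ci$estimate) > 1)
            paste0(label, ":", names(ci$estimate)[i]) else label,
          estimate = unname(ci$estimate[i]),
          lower = unname(ci$lower[i]), upper = unname(ci$upper[i]))
    }
    addCi("meanR_within",
          function(s) floweringSynchrony(s, "within")$meanR)
    addCi("meanR_between",
          function(s) floweringSynchrony(s, "between")$meanR)
    addCi("meanR_overall",
          function(s) floweringSynchrony(s, "overall")$meanR)
    addCi("P_hybrid_formation", function(s)
      hybridFormationProbability(s, pair[1], pair[2], Ns[[1]], Ns[[2]])$P)
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, file.path(cfg$outDir, "phenology.csv"),
                     row.names = FALSE)
    tab
  })
  report$phenology <- phen

  # ---- quantitative traits -------------------------------------------------
  quant <- stage("traits", {
    tt <- traitTab
    # group pure individuals by their truth/input lineage label
    grpCol <- tt$lineage
    pureSel <- if (!is.null(truth)) truth$type[match(tt$individual,
                                                     truth$individual)] ==
                 "pure" else !grepl(":", grpCol)
    tt <- tt[pureSel, ]
    grp <- grpCol[pureSel]
    numCols <- setdiff(names(tt)[vapply(tt, is.numeric, TRUE)],
                       c("herbivory_damaged", "herbivory_total"))
    rows <- lapply(numCols, function(tr) {
      a <- anovaOneway(tt[[tr]], grp)
      lt <- tukeyHsd(tt[[tr]], grp, alpha = cfg$alpha)$letters
      data.frame(trait = tr, F = a$F, p = a$p, sigma2B = a$sigma2B,
                 sigma2W = a$sigma2W,
                 letters = paste(names(lt), lt, sep = "=",
                                 collapse = ";"))
    })
    anovaTab <- do.call(rbind, rows)
    pstRes <- pstFromTrait(tt, "first_flowering", groups = "lineage",
                           c = cfg$c, h2 = cfg$h2)
    glmRes <- quasibinomialGlm(tt$herbivory_damaged, tt$herbivory_total,
                               grp)
    utils::write.csv(anovaTab, file.path(cfg$outDir, "traits_anova.csv"),
                     row.names = FALSE)
    utils::write.csv(glmRes$contrasts,
                     file.path(cfg$outDir, "herbivory_glm.csv"),
                     row.names = FALSE)
    list(anova = anovaTab, pst = pstRes, glm = glmRes)
  })
  report$traits <- list(
    anova = quant$anova,
    pstFirstFlowering = quant$pst$pst,
    herbivoryDispersion = quant$glm$dispersion)

  # ---- report --------------------------------------------------------------
  jsonlite::write_json(report, file.path(cfg$outDir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  md <- c("# cryptolin pipeline report", "",
          paste0("- seed: ", cfg$seed),
          paste0("- individuals: ", n),
          paste0("- best K (delta-K): ", report$cluster$bestK),
          paste0("- hybrids called: ", report$hybrids$nCalled,
                 sprintf(" (%.1f%%)", 100 * report$hybrids$fraction)),
          paste0("- multilocus theta: ",
                 sprintf("%.3f", report$fst$theta)),
          paste0("- PST (first flowering): ",
                 sprintf("%.3f", report$traits$pstFirstFlowering)))
  writeLines(md, file.path(cfg$outDir, "report.md"))
  invisible(report)
}
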