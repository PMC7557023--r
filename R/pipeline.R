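#' Run the full diversity-analysis pipeline
#'
#' Orchestrates the analysis arms (`pedigree`, `roh`, `variants`, `mtdna`)
#' from a single configuration, writing plain TSV reports plus, for every
#' report, a JSON provenance sidecar echoing the inputs, every effective
#' parameter, the package version and the seed, so that a rerun with the
#' same configuration reproduces the outputs byte for byte.  Arms fail
#' independently: reports of completed arms are retained and an error
#' naming the failed stage(s) is raised at the end.
#'
#' Configuration keys (unknown keys are rejected):
#' \describe{
#'   \item{out_dir}{output directory (created if needed).}
#'   \item{seed}{integer seed recorded in the provenance sidecars.}
#'   \item{pedigree}{`file` (CSV), optional `mk_reference` (file of ids,
#'     one per line), `generations` (completeness depth, default 5),
#'     `mk_lower`/`mk_upper` (colour-group thresholds).}
#'   \item{roh}{`ped`/`map` (PLINK text), optional `merge_ped`/`merge_map`
#'     (second array), `hwe_alpha`, `sharing_threshold`, `mds_k`, and any
#'     [RohParams()] argument under `params`.}
#'   \item{variants}{`table` (aggregated TSV), `cohort_n`, `control_n`,
#'     optional `genes` (candidate list), `ctrl_max`, `fold`.}
#'   \item{mtdna}{`variants` (TSV), `defs` (haplogroup definitions TSV).}
#' }
#'
#' @param config a named list as above, or the path to a YAML file.
#' @return (invisibly) list of per-arm results and written file paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("out_dir", "seed", "pedigree", "roh", "variants", "mtdna")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  outDir <- config$out_dir %||% stop("config must name an out_dir")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)

  sidecar <- function(path, inputs, params) {
    prov <- list(report = basename(path), inputs = inputs,
                 parameters = params,
                 package = "breedscope",
                 version = as.character(utils::packageVersion("breedscope")),
                 seed = seed)
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  results <- list()
  failures <- character(0)
  runArm <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      failures[[length(failures) + 1]] <<-
        paste0(name, ": ", conditionMessage(e))
      message("stage '", name, "' failed: ", conditionMessage(e))
      NULL
    })
    results[[name]] <<- res
  }

  if (!is.null(config$pedigree)) runArm("pedigree", function() {
    cfg <- checkKeys(config$pedigree, c("file", "mk_reference", "generations",
                                        "mk_lower", "mk_upper"), "pedigree")
    gens <- cfg$generations %||% 5
    lo <- cfg$mk_lower %||% 0.31
    hi <- cfg$mk_upper %||% 0.32
    ped <- readPedigree(cfg$file)
    K <- kinshipTabular(ped)
    Fped <- inbreedingFped(ped)
    ref <- if (!is.null(cfg$mk_reference)) readLines(cfg$mk_reference)
           else kinshipIds(K)
    mk <- meanKinship(K, ref)
    grp <- mkColorGroups(mk, lo, hi)
    comp <- pedigreeCompleteness(ped, gens)
    rec <- pedigreeRecords(ped)
    perId <- data.frame(id = rec$id, F_PED = Fped[rec$id],
                        MK = mk[rec$id], MK_group = as.character(grp[rec$id]),
                        completeness = comp[rec$id])
    f1 <- writeTsv(perId, file.path(outDir, "pedigree_per_id.tsv"))
    yr <- as.integer(format(rec$birth_date, "%Y"))
    perYear <- do.call(rbind, lapply(split(seq_along(yr)[!is.na(yr)],
                                           yr[!is.na(yr)]), function(i)
      data.frame(year = yr[i][1], n = length(i),
                 mean_F_PED = mean(Fped[rec$id[i]]))))
    f2 <- writeTsv(perYear, file.path(outDir, "pedigree_per_year.tsv"))
    contrib <- founderContribution(ped)
    f3 <- writeTsv(data.frame(founder = names(contrib),
                              contribution = contrib),
                   file.path(outDir, "founder_contribution.tsv"))
    params <- list(generations = gens, mk_lower = lo, mk_upper = hi,
                   mk_reference_size = length(ref))
    for (f in c(f1, f2, f3)) sidecar(f, cfg["file"], params)
    list(files = c(f1, f2, f3), n_animals = length(ped))
  })

  if (!is.null(config$roh)) runArm("roh", function() {
    cfg <- checkKeys(config$roh, c("ped", "map", "merge_ped", "merge_map",
                                   "hwe_alpha", "sharing_threshold", "mds_k",
                                   "params"), "roh")
    g <- readPlinkText(cfg$ped, cfg$map)
    if (!is.null(cfg$merge_ped))
      g <- mergeArrays(g, readPlinkText(cfg$merge_ped, cfg$merge_map))
    alpha <- cfg$hwe_alpha %||% 1e-4
    g <- qcFilter(g, hweAlpha = alpha)
    params <- do.call(RohParams, cfg$params %||% list())
    segs <- callRoh(g, params)
    segDf <- data.frame(IID = mcols(segs)$individual,
                        CHR = as.character(seqnames(segs)),
                        POS1 = start(segs), POS2 = end(segs),
                        KB = mcols(segs)$length_kb,
                        NSNP = mcols(segs)$n_snps)
    f1 <- writeTsv(segDf, file.path(outDir, "roh_segments.tsv"))
    froh <- fRoh(segs, coveredAutosomeKb(g), individuals = colnames(g))
    f2 <- writeTsv(data.frame(IID = names(froh), F_ROH = froh),
                   file.path(outDir, "froh.tsv"))
    scan <- rohSharingScan(segs, g, threshold = cfg$sharing_threshold)
    f3 <- writeTsv(setNames(scan$per_snp, c("CHR", "BP", "FRACTION")),
                   file.path(outDir, "roh_sharing.tsv"))
    k <- cfg$mds_k %||% 2
    mds <- classicalMds(ibsDistance(g), k = k)
    f4 <- writeTsv(data.frame(IID = rownames(mds$coordinates),
                              mds$coordinates),
                   file.path(outDir, "mds_coordinates.tsv"))
    prm <- list(hwe_alpha = alpha, mds_k = k,
                sharing_threshold = cfg$sharing_threshold,
                window_snps = params@windowSnps,
                window_het = params@windowHet,
                window_missing = params@windowMissing,
                window_hit_threshold = params@windowHitThreshold,
                min_snps = params@minSnps, min_kb = params@minKb,
                max_gap_kb = params@maxGapKb,
                density_kb_per_snp = params@densityKbPerSnp)
    for (f in c(f1, f2, f3, f4))
      sidecar(f, cfg[intersect(names(cfg),
                               c("ped", "map", "merge_ped", "merge_map"))],
              prm)
    list(files = c(f1, f2, f3, f4), n_snps = nrow(g), n_segments = length(segs))
  })

  if (!is.null(config$variants)) runArm("variants", function() {
    cfg <- checkKeys(config$variants, c("table", "cohort_n", "control_n",
                                        "genes", "ctrl_max", "fold"),
                     "variants")
    tbl <- readVariantTable(cfg$table, cfg$cohort_n, cfg$control_n)
    ctrlMax <- cfg$ctrl_max %||% 0.10
    fold <- cfg$fold %||% 2
    files <- character(0)
    files <- c(files, writeTsv(privateVariantFilter(tbl),
                               file.path(outDir, "variants_private.tsv")))
    files <- c(files, writeTsv(rareVariantFilter(tbl),
                               file.path(outDir, "variants_rare.tsv")))
    enr <- enrichmentFilter(tbl, high = ctrlMax, fold = fold)
    if (!is.null(cfg$genes))
      enr <- candidateGeneFilter(enr, readGeneList(cfg$genes))
    files <- c(files, writeTsv(enr,
                               file.path(outDir, "variants_enriched.tsv")))
    prm <- list(cohort_n = cfg$cohort_n, control_n = cfg$control_n,
                ctrl_max = ctrlMax, fold = fold,
                genes = cfg$genes)
    for (f in files) sidecar(f, cfg["table"], prm)
    list(files = files, n_variants = nrow(tbl),
         n_enriched = nrow(enr), n_enriched_genes = distinctGeneCount(enr))
  })

  if (!is.null(config$mtdna)) runArm("mtdna", function() {
    cfg <- checkKeys(config$mtdna, c("variants", "defs"), "mtdna")
    mt <- readMtVariants(cfg$variants)
    mt$heteroplasmy_pct <- round(heteroplasmy(mt$depth_alt, mt$depth_total))
    f1 <- writeTsv(mt, file.path(outDir, "mtdna_heteroplasmy.tsv"))
    files <- f1
    if (!is.null(cfg$defs)) {
      defs <- readHaplogroupDefs(cfg$defs)
      files <- c(files, writeTsv(assignHaplogroups(mt, defs),
                                 file.path(outDir, "mtdna_haplogroups.tsv")))
    }
    for (f in files) sidecar(f, cfg[c("variants", "defs")], list())
    list(files = files, n_variants = nrow(mt))
  })

  if (length(failures))
    stop("pipeline stage(s) failed -- completed reports were retained:\n  ",
         paste(failures, collapse = "\n  "))
  invisible(results)
}

checkKeys <- function(cfg, known, arm) {
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown key(s) in '", arm, "' config: ",
         paste(bad, collapse = ", "))
  cfg
}
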