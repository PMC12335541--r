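#' Run the full residual-methylation analysis pipeline
#'
#' Configuration-driven orchestration of simulate -> RMR calling ->
#' kinetics -> DMR calling -> non-CpG analysis -> enrichment, writing every
#' stage's outputs under \code{outdir} with stable names plus a
#' machine-readable \code{summary.json}. All randomness flows from the
#' single top-level seed; per-stage seeds are derived deterministically and
#' recorded in the summary.
#'
#' The YAML config has three optional sections: \code{simulation}
#' (overrides to \code{\link{simulation_config}} fields), \code{params}
#' (overrides to \code{\link{analysis_params}} fields) and \code{stages}
#' (subset of \code{simulate, rmr, kinetics, dmr, noncpg, enrichment};
#' later stages depend on \code{simulate}). A missing or \code{NULL} config
#' runs everything with defaults.
#'
#' @param config Path to a YAML config file, a config list, or \code{NULL}
#'   for defaults.
#' @param seed Top-level integer seed.
#' @param outdir Output directory.
#' @return Invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(config = NULL, seed = 1L, outdir = "pipeline_out") {
  cfg <- if (is.character(config)) yaml::read_yaml(config)
         else if (is.null(config)) list() else config
  known <- c("simulation", "params", "stages")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         " (expected: ", paste(known, collapse = ", "), ")")
  }
  stages_req <- cfg$stages %||%
    c("simulate", "rmr", "kinetics", "dmr", "noncpg", "enrichment")
  bad <- setdiff(stages_req, c("simulate", "rmr", "kinetics", "dmr",
                               "noncpg", "enrichment"))
  if (length(bad)) stop("unknown pipeline stage(s): ", paste(bad, collapse = ", "))

  sim_over <- cfg$simulation %||% list()
  if (length(sim_over)) {
    bad <- setdiff(names(sim_over), names(formals(simulation_config)))
    if (length(bad)) stop("unknown simulation key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(sim_over$contigs)) sim_over$contigs <- unlist(sim_over$contigs)
  if (!is.null(sim_over$te_families)) {
    sim_over$te_families <- as.data.frame(sim_over$te_families)
  }
  par_over <- cfg$params %||% list()
  if (length(par_over)) {
    bad <- setdiff(names(par_over), names(formals(analysis_params)))
    if (length(bad)) stop("unknown params key(s): ", paste(bad, collapse = ", "))
  }

  seed <- as.integer(seed)
  sim_over$seed <- seed
  scfg <- do.call(simulation_config, sim_over)
  params <- do.call(analysis_params, par_over)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "pipeline.log")
  logf <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  }
  unlink(log_path)
  summary <- list(seed = seed, stages = stages_req,
                  params = unclass(params),
                  derived_seeds = list())

  dseed <- function(k) (seed * 1000L + k) %% 2147483647L

  # ---- simulate -------------------------------------------------------
  logf("[simulate] building genome (seed %d)", seed)
  genome <- build_synthetic_genome(scfg)
  end_stage <- scfg$erasure_end_stage
  meths <- list()
  k <- 0L
  for (st in scfg$stages) {
    k <- k + 1L
    meths[[paste0(st, "_female_WT")]] <-
      simulate_stage_methylome(genome, scfg, st, "WT", "female", dseed(k))
  }
  extra <- list(
    c(end_stage, "male", "WT"),
    c(end_stage, "female", "Uhrf2KO"),
    c(end_stage, "female", "Dnmt1cKO"),
    c(scfg$stages[length(scfg$stages)], "male", "WT"))
  for (e in extra) {
    k <- k + 1L
    meths[[paste(e[1], e[2], e[3], sep = "_")]] <-
      simulate_stage_methylome(genome, scfg, e[1], e[3], e[2], dseed(k))
  }
  summary$derived_seeds$simulate <- dseed(seq_len(k))
  if ("simulate" %in% stages_req) {
    write_simulation(genome, meths, outdir)
    logf("[simulate] wrote %d methylomes, %d CpG sites, %d features",
         length(meths), nrow(genome$sites), nrow(genome$features))
  }
  summary$n_cpg_sites <- nrow(genome$sites)
  summary$n_features <- nrow(genome$features)

  wt_end_f <- meths[[paste0(end_stage, "_female_WT")]]
  wt_end_m <- meths[[paste0(end_stage, "_male_WT")]]
  resistant <- genome$features[genome$features$compartment == "resistant_te", ]

  # ---- rmr ------------------------------------------------------------
  rmrs_f <- NULL
  if ("rmr" %in% stages_req) {
    rmrs_f <- call_rmrs(scan_windows(wt_end_f, params), wt_end_f, params)
    rmrs_m <- call_rmrs(scan_windows(wt_end_m, params), wt_end_m, params)
    write_regions_bed(rmrs_f, file.path(outdir, "rmrs_female.bed"))
    write_regions_bed(rmrs_m, file.path(outdir, "rmrs_male.bed"))
    common <- intersect_rmr_cpgs(rmrs_f, rmrs_m, wt_end_f)
    vn <- venn_overlap(rmrs_f, rmrs_m)
    ko <- meths[[paste0(end_stage, "_female_Uhrf2KO")]]
    rmrs_ko <- call_rmrs(scan_windows(ko, params), ko, params)
    rec <- rmr_recovery(rmrs_f, resistant)
    summary$rmr <- list(
      n_female = nrow(rmrs_f), n_male = nrow(rmrs_m),
      n_common_cpgs = nrow(common), venn = vn,
      n_uhrf2ko = nrow(rmrs_ko),
      sensitivity = rec$sensitivity, base_precision = rec$precision)
    logf("[rmr] %d female / %d male RMRs, %d common CpGs, %d in Uhrf2KO",
         nrow(rmrs_f), nrow(rmrs_m), nrow(common), nrow(rmrs_ko))
  }

  # ---- kinetics -------------------------------------------------------
  if ("kinetics" %in% stages_req) {
    erasure_idx <- seq_len(match(end_stage, scfg$stages))
    series <- meths[paste0(scfg$stages[erasure_idx], "_female_WT")]
    epb <- series[[1L]]
    refs <- select_reference_cpgs(epb, wt_end_f, params)
    ref_traj <- build_trajectory(series, refs, target_id = "reference")
    cls <- classify_features(series, ref_traj, genome, params)
    summary$kinetics <- list(
      n_reference_cpgs = nrow(refs),
      confusion = as.list(as.data.frame(cls$confusion)),
      accuracy = cls$accuracy)
    utils::write.table(cls$table, file.path(outdir, "kinetics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("[kinetics] accuracy %.3f over %d targets", cls$accuracy,
         nrow(cls$table))
  }

  # ---- dmr ------------------------------------------------------------
  if ("dmr" %in% stages_req) {
    ko <- meths[[paste0(end_stage, "_female_Uhrf2KO")]]
    dmrs <- call_dmrs(wt_end_f, ko, params)
    write_regions_bed(dmrs, file.path(outdir, "dmrs_wt_vs_uhrf2ko.bed"))
    tef <- dmr_te_fraction(dmrs, genome$features[grepl("te", genome$features$compartment), ])
    hypo <- dmrs[dmrs$direction == "hypo", , drop = FALSE]
    hit <- if (nrow(hypo)) IRanges::overlapsAny(regions_granges(resistant),
                                                regions_granges(hypo))
           else rep(FALSE, nrow(resistant))
    summary$dmr <- list(
      n_dmrs = nrow(dmrs), n_hypo = nrow(hypo),
      n_hyper = sum(dmrs$direction == "hyper"),
      resistant_copy_recovery = mean(hit),
      te_fraction = as.list(stats::setNames(tef$fraction, tef$direction)),
      mean_abs_diff = if (nrow(hypo)) mean(abs(hypo$diff)) else NA_real_)
    logf("[dmr] %d DMRs (%d hypo), resistant recovery %.3f",
         nrow(dmrs), nrow(hypo), mean(hit))
  }

  # ---- noncpg ---------------------------------------------------------
  if ("noncpg" %in% stages_req) {
    male_last <- meths[[paste(scfg$stages[length(scfg$stages)], "male", "WT",
                              sep = "_")]]
    ch <- ch_site_table(male_last)
    pfm <- context_frequency_matrix(male_last, genome,
                                    min_level = params$ch_min_level)
    utils::write.table(
      cbind(base = rownames(pfm), as.data.frame(pfm)),
      file.path(outdir, "ch_context_matrix.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    coup <- cpa_cpg_coupling(male_last, params$window_size)
    pass <- ch[ch$level > params$ch_min_level, ]
    summary$noncpg <- list(
      context_summary = as.list(as.data.frame(attr(ch, "summary"))),
      ca_fraction_passing = mean(pass$context == "CA"),
      cpa_cpg_spearman = coup$rho, n_coupling_windows = coup$n)
    logf("[noncpg] %d CH calls, CA fraction %.3f, rho %.3f",
         nrow(ch), mean(pass$context == "CA"), coup$rho)
  }

  # ---- enrichment -----------------------------------------------------
  if ("enrichment" %in% stages_req) {
    if (is.null(rmrs_f)) {
      rmrs_f <- call_rmrs(scan_windows(wt_end_f, params), wt_end_f, params)
    }
    signal <- data.frame(chrom = resistant$chrom, start = resistant$start,
                         end = resistant$end, value = 1)
    prof <- metaprofile(signal, rmrs_f, genome$contigs,
                        flank = params$flank, n_bins = 100L)
    genomic_mean <- sum((signal$end - signal$start) * signal$value) /
      sum(genome$contigs)
    shuf <- shuffle_regions(rmrs_f, genome$contigs, seed = dseed(900L))
    prof_null <- metaprofile(signal, shuf, genome$contigs,
                             flank = params$flank, n_bins = 100L)
    mid <- c(50L, 51L)
    summary$enrichment <- list(
      central_peak_ratio = mean(prof[mid]) / genomic_mean,
      null_max_ratio = max(prof_null) / genomic_mean)
    utils::write.table(
      data.frame(offset = names(prof), observed = as.numeric(prof),
                 shuffled = as.numeric(prof_null)),
      file.path(outdir, "metaprofile.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    logf("[enrichment] central peak %.2fx genomic mean",
         mean(prof[mid]) / genomic_mean)
  }

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recovery of planted resistant copies by called RMRs
#'
#' @param rmrs Called RMR data.frame.
#' @param resistant Feature data.frame of truly resistant copies.
#' @return List: \code{sensitivity} (fraction of resistant copies
#'   intersecting an RMR) and \code{precision} (fraction of RMR bases lying
#'   inside resistant copies).
#' @export
rmr_recovery <- function(rmrs, resistant) {
  if (!nrow(rmrs)) {
    return(list(sensitivity = 0, precision = NA_real_))
  }
  gr_r <- regions_granges(rmrs)
  gr_t <- GenomicRanges::reduce(regions_granges(resistant))
  sens <- mean(IRanges::overlapsAny(gr_t, gr_r))
  inter <- GenomicRanges::intersect(gr_r, gr_t)
  prec <- sum(IRanges::width(inter)) / sum(IRanges::width(gr_r))
  list(sensitivity = sens, precision = prec)
}

# classify every feature (and background control tiles) against the
# reference trajectory; returns truth-vs-call confusion
classify_features <- function(series, ref_traj, genome, params,
                              n_background = 30L) {
  f <- genome$features
  truth_map <- c(resistant_te = "resistant", nonresistant_te = "erased",
                 delayed_promoter = "delayed", control_promoter = "erased")
  targets <- data.frame(chrom = f$chrom, start = f$start, end = f$end,
                        name = f$name, truth = truth_map[f$compartment])
  # background control regions: tiles around background CpGs, kept clear of
  # annotated features so their trajectories reflect the background alone
  bg <- genome$sites[genome$sites$compartment == "background", ]
  near <- IRanges::overlapsAny(
    GenomicRanges::GRanges(bg$chrom,
                           IRanges::IRanges(start = bg$pos + 1L, width = 1L)),
    GenomicRanges::GRanges(f$chrom,
                           IRanges::IRanges(start = pmax(f$start - 1000L, 0L) + 1L,
                                            end = f$end + 1000L)))
  bg <- bg[!near, , drop = FALSE]
  idx <- round(seq(1L, nrow(bg), length.out = n_background))
  targets <- rbind(targets, data.frame(
    chrom = bg$chrom[idx], start = pmax(bg$pos[idx] - 1000L, 0L),
    end = bg$pos[idx] + 1000L,
    name = sprintf("background_%d", seq_along(idx)), truth = "erased"))

  call <- vapply(seq_len(nrow(targets)), function(i) {
    tr <- build_trajectory(series, targets[i, c("chrom", "start", "end")],
                           target_id = targets$name[i])
    if (any(tr$n_cpg == 0L)) return(NA_character_)
    classify_persistence(tr, ref_traj, params)
  }, character(1L))
  targets$call <- call
  ok <- !is.na(call)
  confusion <- table(truth = targets$truth[ok], call = targets$call[ok])
  list(table = targets,
       confusion = confusion,
       accuracy = mean(targets$truth[ok] == targets$call[ok]))
}
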