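#' Configuration for the stage-resolved methylome simulator
#'
#' The simulator emulates the statistical structure of bisulfite methylomes
#' sampled across germline reprogramming: a globally demethylating background
#' (epiblast-high erasing to ~5% by E13.5), transposable-element copies that
#' resist erasure and retain ~50% methylation, CpG-island promoters whose
#' demethylation lags the genome by a configurable number of stages,
#' male-specific remethylation after E14.5 with coupled CpA methylation, and
#' mutant genotypes that erase TE resistance fully (\code{Uhrf2KO}) or
#' mosaically (\code{Dnmt1cKO}, an aggregate-level cell mixture).
#'
#' Default levels are mid-range choices within the effect sizes reported for
#' mouse PGCs: whole-genome E13.5 methylation ~5%, resistant ERV/IAP copies
#' ~50% (reported range 40-60%), Uhrf2-null residue 3% (reported 2-4%), and a
#' mosaic conditional-deletion efficiency of 0.7 so that the Dnmt1-cKO
#' resistant-TE mixture sits at 17.1% (reported 10-20%).
#'
#' @param contigs Named numeric vector of contig lengths (default one 2 Mb
#'   contig).
#' @param te_families Data.frame with columns \code{family}, \code{n_copies},
#'   \code{copy_length}, \code{resistant} (logical), \code{level} (the
#'   maintained level of resistant copies; ignored for non-resistant ones).
#' @param n_delayed_promoters,n_control_promoters Number of CpG-island
#'   promoters with delayed demethylation kinetics and of always-unmethylated
#'   control CGI promoters.
#' @param promoter_length CGI promoter length in bp.
#' @param background_cpg_spacing Mean distance in bp between background CpGs
#'   (exponential gaps).
#' @param te_cpg_spacing,cgi_cpg_spacing Regular CpG spacing inside TE copies
#'   and CGI promoters (CGIs are CpG-dense: at least one CpG per 20 bp).
#' @param stages Ordered stage labels, first label being the pre-erasure
#'   reference tissue (epiblast).
#' @param background_schedule Named vector of true background CpG levels per
#'   stage; must be non-increasing through the erasure endpoint.
#' @param erasure_end_stage Stage at which global erasure is complete
#'   (default \code{"E13.5"}).
#' @param male_remeth_schedule Named vector of male background levels for
#'   remethylating stages; ignored for female samples.
#' @param remeth_tile_size,remeth_tile_min,remeth_tile_max Male remethylation
#'   is regionally heterogeneous: each tile of \code{remeth_tile_size} bp
#'   gets a uniform multiplier in \code{[remeth_tile_min, remeth_tile_max]}
#'   applied to the remethylation level.
#' @param promoter_lag Number of stages by which delayed promoters lag the
#'   background erasure schedule.
#' @param control_promoter_level Constant level of control CGI promoters.
#' @param m_res Default maintained level of resistant TE copies.
#' @param ko_level Residual level of resistant copies in the full knockout.
#' @param mixture_efficiency Fraction of cells carrying the conditional
#'   deletion in the mosaic knockout.
#' @param coverage_mean,coverage_dispersion Negative-binomial read depth
#'   model (dispersion is the NB size parameter; smaller = more overdispersed,
#'   emulating RRBS depth heterogeneity).
#' @param min_depth Depth filter applied to simulated calls.
#' @param kappa_cpa CpA coupling constant: CpA true level is
#'   \code{kappa_cpa} times the local CpG level in remethylating male stages.
#' @param ch_baseline_level True level of CC/CT sites (near zero).
#' @param ch_site_fraction Fraction of genomic CH positions that are emitted
#'   as calls. Bisulfite sequencing reports every cytosine, so the default
#'   keeps all CH sites; lower values subsample for speed at the cost of
#'   noisier window-level CH summaries.
#' @param mspi_spacing Mean spacing in bp of planted MspI (CCGG) sites.
#' @param seed Integer seed controlling genome construction.
#'
#' @return A list of class \code{"sim_config"}.
#' @export
simulation_config <- function(
    contigs = c(chr1 = 2e6),
    te_families = data.frame(
      family = c("IAPEz", "L1Md_old"),
      n_copies = c(50L, 30L),
      copy_length = c(5000L, 2000L),
      resistant = c(TRUE, FALSE),
      level = c(0.50, NA)),
    n_delayed_promoters = 30L,
    n_control_promoters = 30L,
    promoter_length = 1000L,
    background_cpg_spacing = 100,
    te_cpg_spacing = 40L,
    cgi_cpg_spacing = 20L,
    stages = c("E7.5-epiblast", "E9.5", "E10.5", "E11.5", "E12.5",
               "E13.5", "E14.5", "E16.5", "E17.5"),
    background_schedule = c("E7.5-epiblast" = 0.75, "E9.5" = 0.55,
                            "E10.5" = 0.50, "E11.5" = 0.25, "E12.5" = 0.10,
                            "E13.5" = 0.05, "E14.5" = 0.05, "E16.5" = 0.05,
                            "E17.5" = 0.05),
    erasure_end_stage = "E13.5",
    male_remeth_schedule = c("E14.5" = 0.15, "E16.5" = 0.45, "E17.5" = 0.75),
    remeth_tile_size = 500L,
    remeth_tile_min = 0.4,
    remeth_tile_max = 1.0,
    promoter_lag = 2L,
    control_promoter_level = 0.02,
    m_res = 0.50,
    ko_level = 0.03,
    mixture_efficiency = 0.7,
    coverage_mean = 30,
    coverage_dispersion = 3,
    min_depth = 8L,
    kappa_cpa = 0.05,
    ch_baseline_level = 0.001,
    ch_site_fraction = 1,
    mspi_spacing = 250,
    seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    length(cfg$contigs) >= 1L, !is.null(names(cfg$contigs)),
    all(cfg$contigs > 0),
    is.data.frame(cfg$te_families),
    all(cfg$te_families$copy_length < min(cfg$contigs)),
    all(cfg$stages %in% names(cfg$background_schedule)),
    length(cfg$stages) >= 2L,
    cfg$erasure_end_stage %in% cfg$stages,
    cfg$coverage_mean >= 0, cfg$coverage_dispersion > 0,
    cfg$background_cpg_spacing > 0, cfg$promoter_lag >= 0L,
    cfg$mixture_efficiency >= 0, cfg$mixture_efficiency <= 1)
  lv <- c(cfg$background_schedule, cfg$male_remeth_schedule, cfg$m_res,
          cfg$ko_level, cfg$control_promoter_level, cfg$ch_baseline_level)
  stopifnot(all(lv >= 0 & lv <= 1))
  class(cfg) <- "sim_config"
  cfg
}

COMPARTMENTS <- c("background", "resistant_te", "nonresistant_te",
                  "delayed_promoter", "control_promoter")

#' True methylation level schedule
#'
#' Ground-truth mean methylation for one compartment at one stage in one
#' genotype. Background and non-resistant TEs follow the monotone erasure
#' schedule (with male remethylation after the erasure endpoint); resistant
#' TEs are maintained at \code{max(m_res, background)}; delayed promoters
#' follow the background schedule shifted \code{promoter_lag} stages later
#' during erasure and rejoin the background at the erasure endpoint; control
#' promoters stay constant. \code{Uhrf2KO} sets resistant copies to
#' \code{ko_level} at all post-epiblast stages; \code{Dnmt1cKO} returns the
#' mosaic mixture \code{eff * ko_level + (1 - eff) * WT}.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param compartment One of \code{"background"}, \code{"resistant_te"},
#'   \code{"nonresistant_te"}, \code{"delayed_promoter"},
#'   \code{"control_promoter"}.
#' @param stage A stage label from \code{config$stages}.
#' @param genotype \code{"WT"}, \code{"Uhrf2KO"} or \code{"Dnmt1cKO"}.
#' @param sex \code{"female"} or \code{"male"} (male switches on the
#'   remethylation schedule).
#' @param m_res Optional per-family override of the resistant level.
#' @return A single level in [0, 1].
#' @export
true_level_schedule <- function(config, compartment, stage,
                                genotype = "WT", sex = "female",
                                m_res = config$m_res) {
  if (!compartment %in% COMPARTMENTS) {
    stop("unknown compartment: ", compartment)
  }
  idx <- match(stage, config$stages)
  if (is.na(idx)) stop("unknown stage: ", stage)
  idx_end <- match(config$erasure_end_stage, config$stages)

  bg_at <- function(s) {
    lev <- unname(config$background_schedule[[s]])
    if (sex == "male" && s %in% names(config$male_remeth_schedule)) {
      lev <- max(lev, unname(config$male_remeth_schedule[[s]]))
    }
    lev
  }
  wt <- switch(compartment,
    background = ,
    nonresistant_te = bg_at(stage),
    resistant_te = max(m_res, bg_at(stage)),
    delayed_promoter = if (idx >= idx_end) bg_at(stage) else
      unname(config$background_schedule[[config$stages[max(idx - config$promoter_lag, 1L)]]]),
    control_promoter = config$control_promoter_level)

  if (compartment == "resistant_te" && idx > 1L) {
    if (genotype == "Uhrf2KO") return(config$ko_level)
    if (genotype == "Dnmt1cKO") {
      eff <- config$mixture_efficiency
      return(eff * config$ko_level + (1 - eff) * wt)
    }
  }
  wt
}

#' Build a synthetic genome with TE and promoter annotations
#'
#' Places non-overlapping TE copies and CGI promoters uniformly at random
#' (rejection sampling), plants a CpG at regular spacing inside features and
#' Poisson-spaced CpGs in the background, removes accidental CG dinucleotides
#' from the random base sequence so the planted sites are the only CpGs under
#' study, and scatters MspI (CCGG) recognition sites for the RRBS
#' representation mask. Deterministic for a fixed config seed.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A list of class \code{"sim_genome"} with elements
#'   \describe{
#'     \item{\code{sequence}}{named character vector, one string per contig}
#'     \item{\code{features}}{\code{\link{feature_set}} with a
#'       \code{compartment} column}
#'     \item{\code{sites}}{data.frame of CpG sites: \code{chrom}, \code{pos}
#'       (0-based, plus-strand C of the dyad), \code{compartment},
#'       \code{family}, \code{m_res}}
#'     \item{\code{ch_sites}}{subsampled CH positions with \code{strand} and
#'       \code{context}}
#'     \item{\code{contigs}}{named contig lengths}
#'   }
#' @export
build_synthetic_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  feats <- list()
  seqs <- character(0)
  sites <- list()
  ch <- list()

  for (ci in seq_along(config$contigs)) {
    contig <- names(config$contigs)[ci]
    L <- as.integer(config$contigs[[ci]])

    # --- feature placement by rejection sampling ---
    spec <- config$te_families
    lens <- c(rep(spec$copy_length, spec$n_copies),
              rep(config$promoter_length,
                  config$n_delayed_promoters + config$n_control_promoters))
    fam <- c(rep(spec$family, spec$n_copies),
             rep("delayed_promoter", config$n_delayed_promoters),
             rep("control_promoter", config$n_control_promoters))
    comp <- c(rep(ifelse(spec$resistant, "resistant_te", "nonresistant_te"),
                  spec$n_copies),
              rep("delayed_promoter", config$n_delayed_promoters),
              rep("control_promoter", config$n_control_promoters))
    mres <- c(rep(ifelse(is.na(spec$level), config$m_res, spec$level),
                  spec$n_copies),
              rep(NA_real_, config$n_delayed_promoters +
                    config$n_control_promoters))
    if (sum(lens) > 0.8 * L) {
      stop("feature placement infeasible: total feature length exceeds ",
           "80% of contig ", contig)
    }
    starts <- integer(length(lens))
    occupied_s <- integer(0)
    occupied_e <- integer(0)
    for (i in seq_along(lens)) {
      ok <- FALSE
      for (try in seq_len(10000L)) {
        s <- sample.int(L - lens[i], 1L) - 1L
        e <- s + lens[i]
        if (!any(s < occupied_e & e > occupied_s)) { ok <- TRUE; break }
      }
      if (!ok) stop("feature placement infeasible on contig ", contig)
      starts[i] <- s
      occupied_s <- c(occupied_s, s)
      occupied_e <- c(occupied_e, e)
    }
    fdf <- data.frame(chrom = contig, start = starts, end = starts + lens,
                      name = sprintf("%s_%d", fam, seq_along(fam)),
                      family = fam, strand = "+",
                      compartment = comp, m_res = mres)
    fdf <- fdf[order(fdf$start), , drop = FALSE]

    # --- CpG site placement ---
    fsites <- lapply(seq_len(nrow(fdf)), function(i) {
      sp <- if (grepl("promoter", fdf$compartment[i])) config$cgi_cpg_spacing
            else config$te_cpg_spacing
      p <- seq(fdf$start[i] + 5L, fdf$end[i] - 3L, by = sp)
      data.frame(chrom = contig, pos = as.integer(p),
                 compartment = fdf$compartment[i], family = fdf$family[i],
                 m_res = fdf$m_res[i])
    })
    n_bg <- ceiling(1.5 * L / config$background_cpg_spacing)
    gaps <- pmax(4, round(stats::rexp(n_bg, 1 / config$background_cpg_spacing)))
    bgpos <- cumsum(gaps)
    bgpos <- bgpos[bgpos < L - 2L]
    inside <- overlaps_any(bgpos, fdf$start, fdf$end)
    bgpos <- bgpos[!inside]
    csites <- rbind(
      do.call(rbind, fsites),
      data.frame(chrom = contig, pos = as.integer(bgpos),
                 compartment = "background", family = "none",
                 m_res = NA_real_))
    csites <- csites[order(csites$pos), , drop = FALSE]
    # planted CpGs occupy [pos, pos+1]; enforce >= 3 bp between C positions
    keep <- c(TRUE, diff(csites$pos) >= 3L)
    csites <- csites[keep, , drop = FALSE]

    # --- sequence assembly ---
    base <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                   prob = c(0.3, 0.2, 0.2, 0.3))
    cg <- which(base[-L] == "C" & base[-1L] == "G")
    if (length(cg)) base[cg + 1L] <- "A"   # scrub accidental CpGs
    base[csites$pos + 1L] <- "C"
    base[csites$pos + 2L] <- "G"

    # plant MspI CCGG sites between CpG sites
    n_cut <- ceiling(1.5 * L / config$mspi_spacing)
    cutpos <- cumsum(pmax(8, round(stats::rexp(n_cut, 1 / config$mspi_spacing))))
    cutpos <- cutpos[cutpos < L - 5L]
    ii <- findInterval(cutpos, csites$pos)
    near <- (ii >= 1L & cutpos - csites$pos[pmax(ii, 1L)] <= 4L) |
      (ii < nrow(csites) & csites$pos[pmin(ii + 1L, nrow(csites))] - cutpos <= 4L)
    cutpos <- cutpos[!near]
    for (q in cutpos) base[(q + 1L):(q + 4L)] <- c("C", "C", "G", "G")

    # --- CH site subsample (positions consistent with the sequence) ---
    is_c_plus <- base == "C" & c(base[-1L], "N") %in% c("A", "C", "T")
    is_c_minus <- base == "G" & c("N", base[-L]) %in% c("T", "G", "A")
    chpos_p <- which(is_c_plus) - 1L
    chpos_m <- which(is_c_minus) - 1L
    if (config$ch_site_fraction < 1) {
      chpos_p <- chpos_p[stats::runif(length(chpos_p)) < config$ch_site_fraction]
      chpos_m <- chpos_m[stats::runif(length(chpos_m)) < config$ch_site_fraction]
    }
    ctx_p <- paste0("C", base[chpos_p + 2L])
    comp_m <- chartr("ACGT", "TGCA", base[chpos_m])   # base 5' on minus strand
    ctx_m <- paste0("C", comp_m)
    chdf <- data.frame(
      chrom = contig,
      pos = c(chpos_p, chpos_m),
      strand = rep(c("+", "-"), c(length(chpos_p), length(chpos_m))),
      context = c(ctx_p, ctx_m))
    chdf <- chdf[chdf$context %in% c("CA", "CC", "CT") &
                   chdf$pos >= 0L & chdf$pos < L, , drop = FALSE]
    chdf <- chdf[order(chdf$pos, chdf$strand), , drop = FALSE]

    seqs[contig] <- paste(base, collapse = "")
    feats[[contig]] <- fdf
    sites[[contig]] <- csites
    ch[[contig]] <- chdf
  }

  features <- do.call(rbind, feats)
  fs <- feature_set(features[c("chrom", "start", "end", "name", "family",
                               "strand")])
  fs$compartment <- features$compartment
  fs$m_res <- features$m_res
  structure(
    list(sequence = seqs, features = fs,
         sites = do.call(rbind, sites), ch_sites = do.call(rbind, ch),
         contigs = config$contigs),
    class = "sim_genome")
}

# vectorized point-in-intervals test (0-based half-open)
overlaps_any <- function(pos, starts, ends) {
  if (!length(starts)) return(rep(FALSE, length(pos)))
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start = pos + 1L, width = 1L),
    IRanges::IRanges(start = starts + 1L, end = ends))
  out <- rep(FALSE, length(pos))
  out[S4Vectors::queryHits(hits)] <- TRUE
  out
}

# per-site true CpG levels for one (stage, genotype, sex), including the
# male remethylation tile heterogeneity
true_site_levels <- function(genome, config, stage, genotype, sex,
                             tile_factors = NULL) {
  sites <- genome$sites
  mres <- ifelse(is.na(sites$m_res), config$m_res, sites$m_res)
  combo <- paste(sites$compartment, mres)
  uc <- !duplicated(combo)
  mu_by_combo <- vapply(which(uc), function(i) {
    true_level_schedule(config, sites$compartment[i], stage,
                        genotype = genotype, sex = sex, m_res = mres[i])
  }, numeric(1L))
  mu <- unname(mu_by_combo[match(combo, combo[uc])])
  remeth <- sex == "male" && stage %in% names(config$male_remeth_schedule)
  if (remeth && !is.null(tile_factors)) {
    tiles <- site_tiles(sites$chrom, sites$pos, config$remeth_tile_size)
    fac <- tile_factors[tiles]
    fac[is.na(fac)] <- 1
    dyn <- sites$compartment %in% c("background", "nonresistant_te",
                                    "delayed_promoter")
    mu[dyn] <- mu[dyn] * fac[dyn]
  }
  pmin(pmax(mu, 0), 1)
}

site_tiles <- function(chrom, pos, tile_size) {
  paste0(chrom, ":", pos %/% tile_size)
}

draw_tile_factors <- function(genome, config) {
  tiles <- unique(site_tiles(
    c(genome$sites$chrom, genome$ch_sites$chrom),
    c(genome$sites$pos, genome$ch_sites$pos), config$remeth_tile_size))
  stats::setNames(
    stats::runif(length(tiles), config$remeth_tile_min,
                 config$remeth_tile_max),
    tiles)
}

#' Simulate one stage/genotype methylome from a synthetic genome
#'
#' Per CpG dyad, read depth is drawn from a negative binomial
#' (\code{coverage_mean}, \code{coverage_dispersion}) and methylated counts
#' from a binomial at the site's true level; calls below the depth filter are
#' dropped. The mosaic conditional knockout is sampled per read from the
#' mixture level, which is distributionally identical to drawing each read
#' from a deleted cell with probability \code{mixture_efficiency}. CH calls
#' (stranded, never merged) are emitted only for remethylating male stages:
#' CpA true levels are \code{kappa_cpa} times the local CpG level, CC/CT
#' sites sit at \code{ch_baseline_level}.
#'
#' @param genome A \code{\link{build_synthetic_genome}} result.
#' @param config The \code{\link{simulation_config}} used to build it.
#' @param stage Stage label.
#' @param genotype \code{"WT"}, \code{"Uhrf2KO"} or \code{"Dnmt1cKO"}.
#' @param sex \code{"female"} or \code{"male"}.
#' @param seed Integer seed for the sampling step.
#' @return A strand-merged \code{\link{methylome}} carrying a \code{truth}
#'   attribute: data.frame of per-site true levels for the emitted calls.
#' @export
simulate_stage_methylome <- function(genome, config, stage,
                                     genotype = "WT", sex = "female",
                                     seed = config$seed) {
  stopifnot(inherits(genome, "sim_genome"), inherits(config, "sim_config"))
  set.seed(as.integer(seed) %% .Machine$integer.max)

  remeth <- sex == "male" && stage %in% names(config$male_remeth_schedule)
  tile_factors <- if (remeth) draw_tile_factors(genome, config) else NULL

  sites <- genome$sites
  mu <- true_site_levels(genome, config, stage, genotype, sex, tile_factors)
  n <- nrow(sites)
  depth <- if (config$coverage_mean <= 0) integer(n) else
    stats::rnbinom(n, size = config$coverage_dispersion,
                   mu = config$coverage_mean)
  nm <- stats::rbinom(n, depth, mu)
  cg <- data.frame(chrom = sites$chrom, pos = sites$pos, strand = "+",
                   context = "CG", n_meth = nm, n_total = depth)
  truth <- data.frame(chrom = sites$chrom, pos = sites$pos, context = "CG",
                      mu = mu, compartment = sites$compartment,
                      family = sites$family)

  calls <- cg
  if (remeth && nrow(genome$ch_sites)) {
    chs <- genome$ch_sites
    # local CpG level: mean true CpG level of the site's tile, so CpA
    # methylation tracks local CpG methylation in every compartment
    tiles_cg <- site_tiles(sites$chrom, sites$pos, config$remeth_tile_size)
    tile_mu <- tapply(mu, tiles_cg, mean)
    tiles <- site_tiles(chs$chrom, chs$pos, config$remeth_tile_size)
    local_cpg <- unname(tile_mu[tiles])
    local_cpg[is.na(local_cpg)] <- mean(mu)
    mu_ch <- ifelse(chs$context == "CA", config$kappa_cpa * local_cpg,
                    config$ch_baseline_level)
    mu_ch <- pmin(pmax(mu_ch, 0), 1)
    d_ch <- if (config$coverage_mean <= 0) integer(nrow(chs)) else
      stats::rnbinom(nrow(chs), size = config$coverage_dispersion,
                     mu = config$coverage_mean)
    ch <- data.frame(chrom = chs$chrom, pos = chs$pos, strand = chs$strand,
                     context = chs$context,
                     n_meth = stats::rbinom(nrow(chs), d_ch, mu_ch),
                     n_total = d_ch)
    calls <- rbind(cg, ch)
    truth <- rbind(truth,
                   data.frame(chrom = chs$chrom, pos = chs$pos,
                              context = chs$context, mu = mu_ch,
                              compartment = "background", family = "none"))
  }

  m <- methylome(calls,
                 sample_id = sprintf("%s_%s_%s", stage, sex, genotype),
                 stage = stage, sex = sex, genotype = genotype,
                 min_depth = config$min_depth, contigs = genome$contigs,
                 merged = TRUE)
  kept <- paste(m$calls$chrom, m$calls$pos, m$calls$context)
  truth <- truth[match(kept, paste(truth$chrom, truth$pos, truth$context)), ,
                 drop = FALSE]
  rownames(truth) <- NULL
  attr(m, "truth") <- truth
  m
}

#' Restrict a methylome to RRBS-representable fragments
#'
#' Reduced-representation libraries size-select MspI fragments; this mask
#' keeps only calls lying in fragments between successive CCGG cut positions
#' whose length falls within \code{[fragment_min, fragment_max]}. The cut
#' position of a CCGG site at 0-based position \code{q} is \code{q + 1} (MspI
#' cleaves C^CGG). Calls upstream of the first cut or downstream of the last
#' cut are outside any fragment and are dropped. A non-positive
#' \code{fragment_min} with infinite \code{fragment_max} disables the mask.
#'
#' @param x A \code{\link{methylome}}.
#' @param genome Named character vector of contig sequences, or a
#'   \code{sim_genome}.
#' @param fragment_min,fragment_max Fragment size selection bounds in bp.
#' @return The masked \code{\link{methylome}}.
#' @export
apply_rrbs_mask <- function(x, genome, fragment_min = 150L,
                            fragment_max = 400L) {
  stopifnot(inherits(x, "methylome"))
  if (inherits(genome, "sim_genome")) genome <- genome$sequence
  if (fragment_min <= 0 && is.infinite(fragment_max)) return(x)

  keep <- rep(FALSE, nrow(x$calls))
  any_cut <- FALSE
  for (contig in unique(x$calls$chrom)) {
    if (is.na(genome[contig])) {
      stop("no sequence available for contig ", contig)
    }
    m <- Biostrings::matchPattern("CCGG",
                                  Biostrings::DNAString(genome[[contig]]))
    cuts <- Biostrings::start(m)       # 1-based match start => 0-based start+1-1; cut at start+1 (0-based) == start (1-based)
    cuts <- sort(unique(cuts))         # 0-based cut position = (start-1) + 1 = start
    if (length(cuts) < 2L) next
    any_cut <- TRUE
    frag_start <- cuts[-length(cuts)]
    frag_end <- cuts[-1L]
    ok <- (frag_end - frag_start) >= fragment_min &
      (frag_end - frag_start) <= fragment_max
    if (!any(ok)) next
    idx <- which(x$calls$chrom == contig)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = x$calls$pos[idx] + 1L, width = 1L),
      IRanges::IRanges(start = frag_start[ok] + 1L, end = frag_end[ok]))
    keep[idx[unique(S4Vectors::queryHits(hits))]] <- TRUE
  }
  if (!any_cut) warning("no CCGG sites found; returning empty methylome")
  x$calls <- x$calls[keep, , drop = FALSE]
  rownames(x$calls) <- NULL
  x
}

#' Write simulator outputs to disk
#'
#' Emits the genome as FASTA, annotations as BED (with compartment labels in
#' the name column), each methylome as a methratio-style TSV readable by
#' \code{\link{read_methylation_table}}, and the per-site truth table as TSV.
#'
#' @param genome A \code{sim_genome}.
#' @param methylomes Named list of \code{\link{methylome}} objects.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the vector of written paths.
#' @export
write_simulation <- function(genome, methylomes, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  fa <- file.path(outdir, "genome.fa")
  seqs <- Biostrings::DNAStringSet(genome$sequence)
  Biostrings::writeXStringSet(seqs, fa)
  paths <- c(paths, fa)

  bed <- file.path(outdir, "features.bed")
  f <- genome$features
  utils::write.table(
    data.frame(f$chrom, f$start, f$end,
               paste(f$name, f$compartment, sep = "|"), 0L, f$strand),
    bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  paths <- c(paths, bed)

  for (nm in names(methylomes)) {
    p <- file.path(outdir, paste0(nm, ".meth.tsv"))
    write_methylome_tsv(methylomes[[nm]], p)
    truth <- attr(methylomes[[nm]], "truth")
    if (!is.null(truth)) {
      tp <- file.path(outdir, paste0(nm, ".truth.tsv"))
      utils::write.table(truth, tp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- c(paths, tp)
    }
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a methylome as a methratio-style TSV
#'
#' Columns: chrom, 1-based position, strand, context, ratio, methylated
#' count, total count; header prefixed with \code{#}. Round-trips through
#' \code{read_methylation_table(dialect = "methratio")}.
#'
#' @param x A \code{\link{methylome}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_methylome_tsv <- function(x, path) {
  stopifnot(inherits(x, "methylome"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#chrom\tpos\tstrand\tcontext\tratio\tn_meth\tn_total", con)
  if (nrow(x$calls)) {
    utils::write.table(
      data.frame(x$calls$chrom, x$calls$pos + 1L, x$calls$strand,
                 x$calls$context, sprintf("%.6g", x$calls$level),
                 x$calls$n_meth, x$calls$n_total),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
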