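#' Analysis parameters for the residual-methylation pipeline
#'
#' Bundles every threshold used by the window scanner, RMR/DMR callers,
#' kinetics selection and non-CpG analysis into one validated object, so a
#' whole analysis can be reproduced from a single parameter record.
#'
#' Defaults are the values used throughout the analyses this package
#' implements: 500 bp sliding windows with a 250 bp offset, at least 4 CpGs
#' per window, residual methylation strictly above 30%, a minimum sequencing
#' depth of 8 reads per CpG, reference-CpG selection at epiblast level > 50%
#' and E13.5 level < 20%, a 2% floor for CH sites entering sequence-context
#' analysis, DMR thresholds of >20% methylation difference at q < 0.01,
#' 5000 bp flanks around region centers for metaprofiles, and the 150-400 bp
#' MspI fragment size selection of RRBS libraries.
#'
#' @param window_size Sliding window width in bp.
#' @param window_step Offset between successive window starts in bp; must not
#'   exceed \code{window_size}.
#' @param min_cpgs_per_window Minimum number of covered CpGs for a window to
#'   be eligible for RMR/DMR calling.
#' @param rmr_min_level Residual methylation threshold; a window qualifies as
#'   residually methylated only if its mean level is strictly greater.
#' @param min_depth Minimum read depth for a cytosine call to be retained.
#' @param ref_hi Epiblast methylation level a reference CpG must strictly
#'   exceed.
#' @param ref_lo E13.5 methylation level a reference CpG must be strictly
#'   below.
#' @param ch_min_level Observed level a CH site must strictly exceed to enter
#'   the sequence-context matrix.
#' @param dmr_min_diff Minimum absolute methylation difference for a DMR.
#' @param dmr_max_q Maximum Benjamini-Hochberg q-value for a DMR.
#' @param flank Half-width in bp of the window around region centers used by
#'   \code{\link{metaprofile}}.
#' @param rrbs_fragment_min,rrbs_fragment_max MspI fragment size selection
#'   bounds in bp for the RRBS representation mask.
#'
#' @return A list of class \code{"analysis_params"}.
#' @examples
#' p <- analysis_params()
#' p$window_size
#' @export
analysis_params <- function(window_size = 500L,
                            window_step = 250L,
                            min_cpgs_per_window = 4L,
                            rmr_min_level = 0.30,
                            min_depth = 8L,
                            ref_hi = 0.50,
                            ref_lo = 0.20,
                            ch_min_level = 0.02,
                            dmr_min_diff = 0.20,
                            dmr_max_q = 0.01,
                            flank = 5000L,
                            rrbs_fragment_min = 150L,
                            rrbs_fragment_max = 400L) {
  p <- list(
    window_size = as.integer(window_size),
    window_step = as.integer(window_step),
    min_cpgs_per_window = as.integer(min_cpgs_per_window),
    rmr_min_level = rmr_min_level,
    min_depth = as.integer(min_depth),
    ref_hi = ref_hi,
    ref_lo = ref_lo,
    ch_min_level = ch_min_level,
    dmr_min_diff = dmr_min_diff,
    dmr_max_q = dmr_max_q,
    flank = as.integer(flank),
    rrbs_fragment_min = as.integer(rrbs_fragment_min),
    rrbs_fragment_max = as.integer(rrbs_fragment_max)
  )
  stopifnot(
    p$window_size > 0L, p$window_step > 0L,
    p$window_step <= p$window_size,
    p$min_cpgs_per_window > 0L, p$min_depth > 0L,
    p$flank > 0L,
    p$rrbs_fragment_min > 0L,
    p$rrbs_fragment_max >= p$rrbs_fragment_min
  )
  for (nm in c("rmr_min_level", "ref_hi", "ref_lo", "ch_min_level",
               "dmr_min_diff", "dmr_max_q")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1) {
      stop(sprintf("'%s' must be a single value in (0, 1)", nm))
    }
  }
  class(p) <- "analysis_params"
  p
}

#' @export
print.analysis_params <- function(x, ...) {
  cat("Analysis parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
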