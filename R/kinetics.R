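#' Select reference CpGs for genome-wide erasure kinetics
#'
#' The genome-wide demethylation curve is anchored on CpGs that start high
#' and end fully erased: methylation strictly above \code{ref_hi} (50%) in
#' the epiblast and strictly below \code{ref_lo} (20%) in E13.5 PGCs,
#' evaluated on positions covered in both samples. Sequences that resist
#' erasure fail the second criterion and are excluded by construction.
#'
#' @param epiblast,e13_5 Strand-merged \code{\link{methylome}} objects.
#' @param params An \code{\link{analysis_params}}.
#' @return Data.frame \code{chrom, pos} of reference CpGs.
#' @export
select_reference_cpgs <- function(epiblast, e13_5,
                                  params = analysis_params()) {
  a <- meth_calls(epiblast, context = "CG")
  b <- meth_calls(e13_5, context = "CG")
  i <- match(paste(a$chrom, a$pos), paste(b$chrom, b$pos))
  shared <- !is.na(i)
  if (!any(shared)) stop("no CpG positions covered in both methylomes")
  sel <- shared & a$level > params$ref_hi
  sel[shared] <- sel[shared] & b$level[i[shared]] < params$ref_lo
  out <- a[which(sel), c("chrom", "pos")]
  rownames(out) <- NULL
  out
}

#' Build a stage-ordered methylation trajectory
#'
#' Summarizes per-CpG levels (median by default, as for genome-wide erasure
#' curves) across an ordered series of methylomes, restricted to a CpG
#' position set or to a genomic region. Stage order is taken from the order
#' of \code{methylomes}, never parsed from stage labels. A stage with zero
#' covered sites gets an undefined level and is flagged.
#'
#' @param methylomes Ordered list of \code{\link{methylome}} objects
#'   (earliest stage first).
#' @param sites Either a data.frame \code{chrom, pos} of CpG positions, or a
#'   single-row region data.frame \code{chrom, start, end}.
#' @param summary \code{"median"} or \code{"mean"}.
#' @param target_id Label for the trajectory.
#' @return An object of class \code{"trajectory"}: data.frame
#'   \code{stage, level, n_cpg} with the target id as attribute.
#' @export
build_trajectory <- function(methylomes, sites, summary = c("median", "mean"),
                             target_id = "target") {
  summary <- match.arg(summary)
  stopifnot(length(methylomes) >= 2L)
  fun <- if (summary == "median") stats::median else mean
  by_region <- all(c("start", "end") %in% names(sites))

  rows <- lapply(methylomes, function(m) {
    stopifnot(inherits(m, "methylome"))
    calls <- meth_calls(m, context = "CG")
    lv <- if (by_region) {
      keep <- IRanges::overlapsAny(calls_granges(calls),
                                   regions_granges(sites))
      calls$level[keep]
    } else {
      i <- match(paste(sites$chrom, sites$pos),
                 paste(calls$chrom, calls$pos))
      calls$level[i[!is.na(i)]]
    }
    data.frame(stage = m$stage, level = if (length(lv)) fun(lv) else NA_real_,
               n_cpg = length(lv))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("trajectory", "data.frame"),
            target_id = target_id, summary = summary)
}

#' Demethylation delay score
#'
#' Mean excess methylation of a target trajectory over a reference
#' trajectory across the intermediate stages (endpoints excluded): positive
#' when the target lags the genome-wide erasure, zero for identical
#' kinetics, negative when the target erases ahead of the reference. The
#' score is antisymmetric in its arguments.
#'
#' @param target,reference \code{trajectory} objects on the same stage axis.
#' @return A single score D.
#' @export
delay_score <- function(target, reference) {
  stopifnot(inherits(target, "trajectory"), inherits(reference, "trajectory"))
  if (!identical(target$stage, reference$stage)) {
    stop("trajectories are not on the same stage axis")
  }
  n <- nrow(target)
  if (n < 3L) stop("need at least one intermediate stage")
  mid <- 2L:(n - 1L)
  mean(target$level[mid] - reference$level[mid])
}

#' Classify erasure kinetics as erased, delayed or resistant
#'
#' Operationalizes the three behaviours seen across germline reprogramming:
#' sequences that resist the demethylation wave (endpoint level still at or
#' above the residual-methylation threshold), sequences with delayed
#' kinetics (they lag the reference by more than \code{delta} on average but
#' still reach erasure below \code{ref_lo}), and fully erased sequences.
#' The trajectory must span the pre-erasure reference tissue through the
#' erasure endpoint (epiblast through E13.5); the final stage is taken as
#' the endpoint.
#'
#' @param target,reference \code{trajectory} objects on the same stage axis,
#'   epiblast first and erasure endpoint (E13.5) last.
#' @param params An \code{\link{analysis_params}}.
#' @param delta Delay-score threshold separating delayed from erased.
#' @return One of \code{"erased"}, \code{"delayed"}, \code{"resistant"}.
#' @export
classify_persistence <- function(target, reference,
                                 params = analysis_params(), delta = 0.15) {
  stopifnot(inherits(target, "trajectory"))
  end_level <- target$level[nrow(target)]
  if (is.na(end_level)) stop("erasure endpoint stage has no covered sites")
  if (end_level >= params$rmr_min_level) return("resistant")
  d <- delay_score(target, reference)
  if (d > delta && end_level < params$ref_lo) return("delayed")
  "erased"
}
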