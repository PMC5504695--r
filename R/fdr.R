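#' Filter PSMs at a target-decoy FDR threshold
#'
#' Sorts PSMs by descending score and keeps the largest score-prefix whose
#' estimated false discovery rate, the concatenated target-decoy estimator
#' `#decoys / #targets`, stays at or below `fdrThreshold`. Decoy rows are
#' removed from the returned table. Filtering is per run by default (each run
#' gets its own cutoff); with `global = TRUE` one cutoff is chosen over the
#' pooled table. Within tied scores decoys are placed first, so a tie at the
#' boundary is treated conservatively.
#'
#' @param psms PSM data.frame with at least `run_id`, `score`, `is_decoy`.
#' @param fdrThreshold PSM-level FDR threshold in (0, 1); default 0.02.
#' @param global estimate one cutoff over all runs instead of per run.
#' @return list with elements:
#'   \describe{
#'     \item{psms}{retained target PSMs;}
#'     \item{cutoffs}{data.frame per filtering unit: `run_id`, `score_cutoff`,
#'       `n_targets`, `n_decoys`, `estimated_fdr`;}
#'     \item{runTotals}{data.frame `run_id`, `sample_id`, `total_spectra` —
#'       the total collected spectra per run before filtering, kept for the
#'       later normalization.}
#'   }
#' @export
filterPsmsByFdr <- function(psms, fdrThreshold = 0.02, global = FALSE) {
  stopifnot(is.data.frame(psms),
            all(c("run_id", "score", "is_decoy") %in% colnames(psms)))
  if (length(fdrThreshold) != 1L || is.na(fdrThreshold) ||
      fdrThreshold <= 0 || fdrThreshold >= 1)
    stop("'fdrThreshold' must lie strictly between 0 and 1")

  runTotals <- as.data.frame(table(run_id = psms$run_id),
                             stringsAsFactors = FALSE)
  colnames(runTotals)[2] <- "total_spectra"
  if ("sample_id" %in% colnames(psms)) {
    runTotals$sample_id <- psms$sample_id[
      match(runTotals$run_id, psms$run_id)]
  } else runTotals$sample_id <- runTotals$run_id

  unitOf <- if (global) rep("all", nrow(psms)) else psms$run_id
  kept <- logical(nrow(psms))
  cutoffs <- NULL
  for (u in unique(unitOf)) {
    idx <- which(unitOf == u)
    sub <- psms[idx, ]
    if (!any(sub$is_decoy))
      stop("no decoy PSMs in '", u, "': FDR is inestimable")
    if (all(sub$is_decoy))
      stop("no target PSMs in '", u, "': FDR is inestimable")
    # decoys first within score ties -> conservative boundary
    ord <- order(-sub$score, !sub$is_decoy)
    d <- cumsum(sub$is_decoy[ord])
    t <- cumsum(!sub$is_decoy[ord])
    ok <- which(t > 0 & d <= fdrThreshold * t)
    if (length(ok)) {
      last <- max(ok)
      prefix <- ord[seq_len(last)]
      kept[idx[prefix]] <- !sub$is_decoy[prefix]
      cut <- sub$score[ord[last]]
      nd <- d[last]; nt <- t[last]
    } else {
      cut <- Inf; nd <- 0L; nt <- 0L
    }
    cutoffs <- rbind(cutoffs, data.frame(
      run_id = u, score_cutoff = cut, n_targets = nt, n_decoys = nd,
      estimated_fdr = if (nt > 0) nd / nt else NA_real_,
      stringsAsFactors = FALSE))
  }
  list(psms = psms[kept, , drop = FALSE], cutoffs = cutoffs,
       runTotals = runTotals[, c("run_id", "sample_id", "total_spectra")])
}
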