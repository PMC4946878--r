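#' Score candidate calls against simulation truth
#'
#' Standard confusion-matrix arithmetic over genes: a planted resistance
#' gene called candidate is a true positive, a non-planted candidate a
#' false positive. Sensitivity is TP over the number of planted genes
#' (`NA` when nothing was planted); FDR is FP/(FP+TP) with the 0/0 case
#' defined as 0 (no calls means no false discoveries).
#'
#' @param calls A `gene_candidates` object from [call_candidates()].
#' @param truth A `simulation_truth` from [simulate_truth()].
#' @return A list of class `recovery_report`: `sensitivity`,
#'   `false_positives`, `fdr`, `tp`, `fn`, `n_planted`, and `per_gene`
#'   (data frame `gene`, `planted`, `called`, `status`).
#' @export
recovery_metrics <- function(calls, truth) {
  stopifnot(inherits(calls, "gene_candidates"),
            inherits(truth, "simulation_truth"))
  universe <- attr(calls, "genes")
  planted <- truth$resistance_genes
  if (length(planted) && !any(planted %in% universe))
    stop("truth and calls have disjoint gene universes")
  missing <- setdiff(planted, universe)
  if (length(missing))
    stop("planted genes absent from the assayed universe: ",
         paste(missing, collapse = ", "))
  called <- calls$gene[calls$candidate]
  is_planted <- universe %in% planted
  is_called <- universe %in% called
  status <- ifelse(is_planted & is_called, "TP",
            ifelse(!is_planted & is_called, "FP",
            ifelse(is_planted, "FN", "TN")))
  tp <- sum(status == "TP")
  fp <- sum(status == "FP")
  fn <- sum(status == "FN")
  structure(list(
    sensitivity = if (length(planted)) tp / length(planted) else NA_real_,
    false_positives = fp,
    fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
    tp = tp, fn = fn, n_planted = length(planted),
    per_gene = data.frame(gene = universe, planted = is_planted,
                          called = is_called, status = status,
                          stringsAsFactors = FALSE)),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery vs simulation truth:\n")
  cat("  planted genes:   ", x$n_planted, "\n")
  cat("  sensitivity:     ",
      if (is.na(x$sensitivity)) "NA (nothing planted)"
      else sprintf("%.3f (%d/%d)", x$sensitivity, x$tp, x$n_planted), "\n")
  cat("  false positives: ", x$false_positives, "\n")
  cat("  FDR:             ", sprintf("%.3f", x$fdr), "\n")
  invisible(x)
}

#' Write a recovery report TSV
#'
#' @param report A `recovery_report`.
#' @param path Output path for the per-gene detail table.
#' @export
write_recovery <- function(report, path) {
  stopifnot(inherits(report, "recovery_report"))
  write.table(report$per_gene, path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Compare replication requirements by simulation
#'
#' Monte-Carlo comparison of the candidate rule under different
#' cross-screen replication requirements (`min_screens`). For each
#' replicate a full experiment is simulated from `sim_params` (with a seed
#' derived from `seed`), and the same counts are called once per
#' `min_screens` value; the mean false-positive count per mode quantifies
#' how demanding replication across independent screens suppresses
#' single-screen off-target/passenger artifacts.
#'
#' @param min_screens_values Integer vector of `min_screens` settings.
#' @param sim_params A [simulation_params()] object (typically
#'   [null_screen_params()], no planted genes).
#' @param n_reps Number of simulated experiments.
#' @param seed Master seed for the replicate seed stream.
#' @param hit_params Base [hit_call_params()]; its `min_screens` is
#'   overridden per mode.
#' @return A data frame: `min_screens`, `mean_false_positives`,
#'   `mean_sensitivity` (NA when nothing planted), `n_reps`.
#' @export
compare_replication_modes <- function(min_screens_values = c(1L, 2L),
                                      sim_params = null_screen_params(),
                                      n_reps = 50L, seed = 1L,
                                      hit_params = hit_call_params()) {
  stopifnot(n_reps >= 1)
  rep_seeds <- spawn_seeds(seed, n_reps)
  modes <- lapply(min_screens_values, function(ms) {
    p <- hit_params
    p$min_screens <- as.integer(ms)
    p
  })
  fp <- matrix(0, nrow = n_reps, ncol = length(modes))
  sens <- matrix(NA_real_, nrow = n_reps, ncol = length(modes))
  for (r in seq_len(n_reps)) {
    sp <- sim_params
    sp$seed <- rep_seeds[r]
    sim <- simulate_screen(sp)
    for (m in seq_along(modes)) {
      fit <- call_candidates(sim$counts, sim$library, modes[[m]])
      rec <- recovery_metrics(fit, sim$truth)
      fp[r, m] <- rec$false_positives
      sens[r, m] <- rec$sensitivity
    }
  }
  data.frame(min_screens = as.integer(min_screens_values),
             mean_false_positives = colMeans(fp),
             mean_sensitivity = colMeans(sens),
             n_reps = as.integer(n_reps))
}
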