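#' Hit-calling parameters
#'
#' Bundles the constants of the enrichment rule used to call candidate genes
#' in a positive-selection screen. With the defaults, an sgRNA is *enriched*
#' in a screen when its survivor read count strictly exceeds
#' `reads_threshold` (1000 reads) **and** is at least `fold_threshold`
#' (3-fold) above the average of its baseline reads; a gene is a *candidate*
#' when at least `min_sgrnas` (2) of its guides are enriched with support
#' spread over at least `min_screens` (2) independent screens.
#'
#' @param reads_threshold Absolute survivor read threshold; the test is
#'   strict (`survivor > reads_threshold`).
#' @param fold_threshold Relative threshold on survivor reads over the
#'   baseline reference; the test is inclusive (`fold >= fold_threshold`).
#' @param min_sgrnas Minimum number of distinct enriched sgRNAs per
#'   candidate gene.
#' @param sgrnas_per_gene Nominal guides per gene in the library (display
#'   only; actual totals are taken from the library).
#' @param min_screens Minimum number of distinct screens contributing
#'   enriched events to a candidate gene.
#' @param baseline_mode How "the average of the baseline read" is formed for
#'   a guide: `"per_guide_pooled"` (default) averages the guide's baseline
#'   counts across all screens; `"per_guide_per_screen"` uses each screen's
#'   own baseline count.
#' @param pseudocount Floor applied to the baseline reference, preventing
#'   division by zero for guides absent at baseline.
#' @param depth_normalize If `TRUE`, counts are converted to reads per
#'   million within each sample before thresholding; the default applies the
#'   thresholds to raw reads, as absolute sequencer read counts.
#' @param per_guide_replication If `TRUE`, a stricter replication mode: only
#'   guides individually enriched in at least `min_screens` screens count
#'   toward the sgRNA vote. The default pools replication at the gene level
#'   (enriched events of the gene must span `min_screens` screens).
#'
#' @return An object of class `hit_call_params`.
#' @examples
#' hit_call_params()
#' hit_call_params(min_screens = 1)
#' @export
hit_call_params <- function(reads_threshold = 1000,
                            fold_threshold = 3,
                            min_sgrnas = 2L,
                            sgrnas_per_gene = 6L,
                            min_screens = 2L,
                            baseline_mode = c("per_guide_pooled",
                                              "per_guide_per_screen"),
                            pseudocount = 1,
                            depth_normalize = FALSE,
                            per_guide_replication = FALSE) {
  baseline_mode <- match.arg(baseline_mode)
  stopifnot(reads_threshold > 0, fold_threshold > 0,
            min_sgrnas >= 1, min_screens >= 1, pseudocount > 0,
            min_sgrnas <= sgrnas_per_gene)
  out <- list(reads_threshold = reads_threshold,
              fold_threshold = fold_threshold,
              min_sgrnas = as.integer(min_sgrnas),
              sgrnas_per_gene = as.integer(sgrnas_per_gene),
              min_screens = as.integer(min_screens),
              baseline_mode = baseline_mode,
              pseudocount = pseudocount,
              depth_normalize = isTRUE(depth_normalize),
              per_guide_replication = isTRUE(per_guide_replication))
  class(out) <- "hit_call_params"
  out
}

#' @export
print.hit_call_params <- function(x, ...) {
  cat("Hit-calling rule:\n")
  cat("  enriched sgRNA: survivor reads >", x$reads_threshold,
      "AND fold >=", x$fold_threshold, "over baseline reference\n")
  cat("  baseline reference:", x$baseline_mode,
      "(pseudocount floor", x$pseudocount, ")\n")
  cat("  candidate gene: >=", x$min_sgrnas, "distinct sgRNAs enriched,",
      "support in >=", x$min_screens, "independent screens",
      if (x$per_guide_replication) "(per-guide replication)" else "", "\n")
  if (x$depth_normalize)
    cat("  thresholds applied to reads-per-million, not raw reads\n")
  invisible(x)
}

# Reads-per-million scaling of one count column within each screen sample.
cpm_scale <- function(counts, col) {
  totals <- tapply(counts[[col]], counts$screen_id, sum)
  totals[totals == 0] <- 1
  counts[[col]] * 1e6 / as.numeric(totals[counts$screen_id])
}

#' Baseline reference for each guide and screen
#'
#' Computes the denominator of the fold-enrichment test: the average of a
#' guide's baseline reads. In `"per_guide_pooled"` mode the guide's baseline
#' counts are averaged across all screens of the experiment (so the
#' reference is common to every screen); in `"per_guide_per_screen"` mode
#' each screen contributes its own baseline count. The result is floored at
#' `params$pseudocount`.
#'
#' @param counts A `screen_counts` table.
#' @param params A [hit_call_params()] object.
#' @return A numeric vector aligned with the rows of `counts`.
#' @export
baseline_reference <- function(counts, params = hit_call_params()) {
  stopifnot(inherits(params, "hit_call_params"))
  baseline <- counts$baseline_count
  if (params$depth_normalize) baseline <- cpm_scale(counts, "baseline_count")
  if (params$baseline_mode == "per_guide_pooled") {
    means <- tapply(baseline, counts$guide_id, mean)
    ref <- as.numeric(means[counts$guide_id])
  } else {
    ref <- as.numeric(baseline)
  }
  pmax(ref, params$pseudocount)
}

#' Apply the per-sgRNA enrichment rule
#'
#' Evaluates the two-part enrichment test for given survivor read counts and
#' baseline references: the absolute test is strict
#' (`survivor > reads_threshold`) and the relative test is inclusive
#' (`survivor / reference >= fold_threshold`). A survivor count of exactly
#' 1000 reads therefore never passes the default absolute test, while a fold
#' of exactly 3 passes the default relative test.
#'
#' @param survivor_count Numeric vector of survivor read counts.
#' @param reference Numeric vector of baseline references (recycled).
#' @param params A [hit_call_params()] object.
#' @return A data frame with columns `fold` and `enriched`.
#' @examples
#' flag_enriched(c(1000, 1001, 5000), c(1, 1, 2000))
#' @export
flag_enriched <- function(survivor_count, reference,
                          params = hit_call_params()) {
  stopifnot(inherits(params, "hit_call_params"), all(reference > 0))
  fold <- survivor_count / reference
  enriched <- (survivor_count > params$reads_threshold) &
    (fold >= params$fold_threshold)
  data.frame(fold = fold, enriched = enriched)
}

#' Per-sgRNA enrichment records for a whole experiment
#'
#' Computes, for every guide in every screen, the baseline reference, the
#' survivor/baseline fold and the enriched flag under the given rule.
#'
#' @param counts A `screen_counts` table.
#' @param library The companion `sgrna_library`.
#' @param params A [hit_call_params()] object.
#' @return A data frame of class `enrichment_records` with columns
#'   `guide_id`, `screen_id`, `gene`, `baseline_count`, `survivor_count`,
#'   `baseline_reference`, `fold`, `enriched`.
#' @export
enrichment_table <- function(counts, library, params = hit_call_params()) {
  counts <- screen_counts(counts, library)
  survivor <- counts$survivor_count
  if (params$depth_normalize) survivor <- cpm_scale(counts, "survivor_count")
  ref <- baseline_reference(counts, params)
  flags <- flag_enriched(survivor, ref, params)
  out <- data.frame(
    guide_id = counts$guide_id,
    screen_id = counts$screen_id,
    gene = library$gene[match(counts$guide_id, library$guide_id)],
    baseline_count = counts$baseline_count,
    survivor_count = counts$survivor_count,
    baseline_reference = ref,
    fold = flags$fold,
    enriched = flags$enriched,
    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_records", "data.frame")
  out
}

#' Write enrichment records to TSV
#'
#' @param records An `enrichment_records` table from [enrichment_table()].
#' @param path Output path.
#' @export
write_enrichment <- function(records, path) {
  out <- as.data.frame(records)
  out$enriched <- as.integer(out$enriched)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Raw log2 gene scores
#'
#' Aggregates a gene's enriched (guide, screen) events into one raw score:
#' the log2 of the mean fold over those events. Taking the mean before the
#' log keeps the score insensitive to how many screens were run. Genes with
#' no enriched event get a raw score of 0 and are flagged `excluded`; they
#' never enter the candidate ranking.
#'
#' @param records An `enrichment_records` table.
#' @return A data frame with one row per gene: `gene`, `n_events`,
#'   `raw_score`, `excluded`.
#' @examples
#' # a single enriched event with fold 8 gives raw score log2(8) = 3
#' @export
gene_raw_scores <- function(records) {
  genes <- unique(records$gene)
  ev <- records[records$enriched, , drop = FALSE]
  n_events <- table(factor(ev$gene, levels = genes))
  mean_fold <- tapply(ev$fold, factor(ev$gene, levels = genes), mean)
  raw <- ifelse(n_events > 0, log2(mean_fold), 0)
  data.frame(gene = genes,
             n_events = as.integer(n_events),
             raw_score = as.numeric(raw),
             excluded = as.integer(n_events) == 0L,
             stringsAsFactors = FALSE)
}

#' Normalize gene scores to the top-scoring hit
#'
#' Divides every positive raw score by the maximum raw score, so the
#' top-scoring gene (the TP53 analogue in the motivating screen) gets
#' exactly 1.0 and all scores lie in (0, 1]. Ties at the maximum all map to
#' 1.0. Genes flagged `excluded` (no enriched events) are dropped.
#'
#' @param raw A data frame from [gene_raw_scores()], or a named numeric
#'   vector of raw scores.
#' @return A named numeric vector of normalized scores over the scored
#'   genes; empty (with a warning) if no gene has a positive raw score.
#' @export
normalize_scores <- function(raw) {
  if (is.data.frame(raw)) {
    keep <- !raw$excluded
    scores <- setNames(raw$raw_score[keep], raw$gene[keep])
  } else {
    scores <- raw
  }
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0L || max(scores) <= 0) {
    warning("no gene with positive raw score; nothing to normalize")
    return(setNames(numeric(0), character(0)))
  }
  scores / max(scores)
}
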