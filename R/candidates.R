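#' Candidate vote for a single gene
#'
#' Applies the replication vote to one gene's enrichment records. In the
#' default (gene-level) mode, `n_enriched_sgrnas` counts distinct guides
#' with at least one enriched event and `n_supporting_screens` counts
#' distinct screens contributing at least one enriched event; the gene is a
#' candidate when both minima in `params` are met. In per-guide replication
#' mode only guides individually enriched in `min_screens` screens count.
#'
#' @param records Enrichment records ([enrichment_table()]) restricted to
#'   or containing the gene.
#' @param gene Gene symbol to evaluate.
#' @param params A [hit_call_params()] object.
#' @return A list with `candidate`, `n_enriched_sgrnas`,
#'   `n_supporting_screens`.
#' @export
call_gene <- function(records, gene, params = hit_call_params()) {
  ev <- records[records$gene == gene & records$enriched, , drop = FALSE]
  if (params$per_guide_replication) {
    screens_by_guide <- tapply(ev$screen_id, ev$guide_id,
                               function(s) length(unique(s)))
    counted <- names(screens_by_guide)[screens_by_guide >= params$min_screens]
    ev <- ev[ev$guide_id %in% counted, , drop = FALSE]
    n_guides <- length(counted)
    n_screens <- length(unique(ev$screen_id))
    candidate <- n_guides >= params$min_sgrnas
  } else {
    n_guides <- length(unique(ev$guide_id))
    n_screens <- length(unique(ev$screen_id))
    candidate <- n_guides >= params$min_sgrnas &&
      n_screens >= params$min_screens
  }
  list(candidate = candidate,
       n_enriched_sgrnas = n_guides,
       n_supporting_screens = n_screens)
}

#' Call candidate genes from screen counts
#'
#' The main entry point of the package: evaluates the per-sgRNA enrichment
#' rule over every guide and screen, aggregates enriched events into log2
#' gene scores normalized to the top-scoring hit, applies the
#' multi-sgRNA/multi-screen replication vote, and returns the ranked
#' candidate table. Only genes with at least one enriched event appear in
#' the table; genes never enriched are excluded from ranking (their count is
#' retained in the object for [summary()]).
#'
#' @param counts A `screen_counts` table (or coercible data frame).
#' @param library The companion `sgrna_library`.
#' @param params A [hit_call_params()] object.
#' @return An object of class `gene_candidates`: a data frame ordered by
#'   rank with columns `gene`, `raw_score`, `normalized_score`,
#'   `n_enriched_sgrnas`, `n_total_sgrnas`, `n_supporting_screens`,
#'   `candidate`, carrying the parameters and per-guide records as
#'   attributes. Ties in `normalized_score` are broken by
#'   `n_enriched_sgrnas` (descending), then gene symbol (ascending).
#' @examples
#' sim <- simulate_screen(simulation_params(n_genes = 20, n_screens = 4,
#'                                          seed = 1))
#' fit <- call_candidates(sim$counts, sim$library)
#' fit
#' @export
call_candidates <- function(counts, library, params = hit_call_params()) {
  stopifnot(inherits(library, "sgrna_library"),
            inherits(params, "hit_call_params"))
  records <- enrichment_table(counts, library, params)
  raw <- gene_raw_scores(records)
  scored <- raw[!raw$excluded, , drop = FALSE]
  norm <- suppressWarnings(normalize_scores(raw))
  per_gene <- lapply(scored$gene, function(g) call_gene(records, g, params))
  totals <- guides_per_gene(library)
  out <- data.frame(
    gene = scored$gene,
    raw_score = scored$raw_score,
    normalized_score = if (length(norm)) as.numeric(norm[scored$gene])
                       else rep(NA_real_, nrow(scored)),
    n_enriched_sgrnas = vapply(per_gene, `[[`, integer(1),
                               "n_enriched_sgrnas"),
    n_total_sgrnas = as.integer(totals[scored$gene]),
    n_supporting_screens = vapply(per_gene, `[[`, integer(1),
                                  "n_supporting_screens"),
    candidate = vapply(per_gene, `[[`, logical(1), "candidate"),
    stringsAsFactors = FALSE)
  out <- rank_candidates(out)
  structure(out,
            class = c("gene_candidates", "data.frame"),
            params = params,
            records = records,
            genes = unique(library$gene),
            n_screens = length(unique(records$screen_id)))
}

#' Rank a candidate table
#'
#' Orders rows by `normalized_score` descending, breaking ties by
#' `n_enriched_sgrnas` descending and then gene symbol ascending.
#'
#' @param table A `gene_candidates` object or compatible data frame.
#' @return The same object with rows reordered and row names reset.
#' @export
rank_candidates <- function(table) {
  ord <- order(-table$normalized_score, -table$n_enriched_sgrnas,
               table$gene, method = "radix")
  out <- table[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.gene_candidates <- function(x, n = 10L, ...) {
  params <- attr(x, "params")
  cat("Candidate genes from", attr(x, "n_screens"), "screen(s):",
      sum(x$candidate), "candidates /", nrow(x), "genes with enriched sgRNAs",
      "(", length(attr(x, "genes")), "genes assayed )\n")
  df <- as.data.frame(x)
  df$normalized_score <- sprintf("%.4f", df$normalized_score)
  df$sgRNAs <- paste0(df$n_enriched_sgrnas, "/", df$n_total_sgrnas)
  show <- df[, c("gene", "normalized_score", "sgRNAs",
                 "n_supporting_screens", "candidate")]
  print.data.frame(head(show, n), row.names = FALSE)
  if (nrow(show) > n) cat("... and", nrow(show) - n, "more genes\n")
  invisible(x)
}

#' @export
summary.gene_candidates <- function(object, ...) {
  params <- attr(object, "params")
  cat("Positive-selection screen hit calling\n")
  print(params)
  cat("Genes assayed:           ", length(attr(object, "genes")), "\n")
  cat("Genes with >=1 enriched sgRNA:", nrow(object), "\n")
  cat("Candidate genes:         ", sum(object$candidate), "\n")
  if (any(object$candidate)) {
    top <- object[object$candidate, ][1L, ]
    cat("Top hit:                 ", top$gene,
        sprintf("(score %.4f, %d/%d sgRNAs, %d screens)\n",
                top$normalized_score, top$n_enriched_sgrnas,
                top$n_total_sgrnas, top$n_supporting_screens))
  }
  invisible(object)
}

#' @export
as.data.frame.gene_candidates <- function(x, ...) {
  out <- x
  attributes(out)[c("params", "records", "genes", "n_screens")] <- NULL
  class(out) <- "data.frame"
  out
}

#' Plot normalized gene scores
#'
#' Horizontal bar plot of the normalized log2 enrichment scores (candidates
#' by default), the usual visual summary of a positive-selection screen.
#'
#' @param x A `gene_candidates` object.
#' @param top Maximum number of genes to show.
#' @param candidates_only Drop non-candidate genes first.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.gene_candidates <- function(x, top = 30L, candidates_only = TRUE, ...) {
  df <- as.data.frame(x)
  if (candidates_only) df <- df[df$candidate, , drop = FALSE]
  if (nrow(df) == 0L) stop("no genes to plot")
  df <- head(df, top)
  df <- df[rev(seq_len(nrow(df))), ]
  graphics::barplot(df$normalized_score, names.arg = df$gene, horiz = TRUE,
                    las = 1, xlab = "log2 sgRNA enrichment (top hit = 1)",
                    xlim = c(0, 1), ...)
  invisible(x)
}

#' Write a candidate table TSV
#'
#' Columns: `gene`, `normalized_score` (4 decimals), `enriched_fraction`
#' (as in "4/6"), `n_supporting_screens`, `candidate` (0/1).
#'
#' @param x A `gene_candidates` object.
#' @param path Output path.
#' @export
write_candidates <- function(x, path) {
  df <- as.data.frame(x)
  out <- data.frame(
    gene = df$gene,
    normalized_score = sprintf("%.4f", df$normalized_score),
    enriched_fraction = paste0(df$n_enriched_sgrnas, "/", df$n_total_sgrnas),
    n_supporting_screens = df$n_supporting_screens,
    candidate = as.integer(df$candidate),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Reference candidate table from the motivating screen
#'
#' The published 27-gene candidate table of the genome-wide centrosome-loss
#' (PLK4-inactivation) survival screen, transcribed as shipped in
#' `inst/extdata/reference_candidates.tsv`: gene symbol, log2 sgRNA
#' enrichment normalized to the top-scoring hit (TP53 = 1.0000) and the
#' number of enriched sgRNAs out of six.
#'
#' @return A data frame with columns `gene`, `normalized_score`,
#'   `n_enriched_sgrnas`, `n_total_sgrnas`.
#' @export
reference_candidates <- function() {
  path <- system.file("extdata", "reference_candidates.tsv",
                      package = "screenvote", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Expand a candidate summary into synthetic screen counts
#'
#' Inverts the pipeline's scoring to rebuild a minimal count experiment that
#' reproduces a published candidate summary: each gene gets a full
#' complement of guides, its `n_enriched_sgrnas` guides receive survivor
#' counts `round(baseline * 2^(log2_top * normalized_score))` in each of
#' `n_screens` screens (all other counts 0), and every baseline count equals
#' `baseline`. Running [call_candidates()] on the result recovers the
#' summary's candidate set, enriched-guide counts and (up to integer
#' rounding of counts, relative error < 2e-5) its normalized scores.
#'
#' @param ref A data frame as returned by [reference_candidates()].
#' @param baseline Baseline read count given to every guide.
#' @param n_screens Number of screens carrying the enriched events.
#' @param log2_top Raw log2 score assigned to a normalized score of 1.
#' @return A list with elements `library` (`sgrna_library`) and `counts`
#'   (`screen_counts`).
#' @export
counts_from_candidates <- function(ref, baseline = 100L, n_screens = 2L,
                                   log2_top = 10) {
  stopifnot(all(c("gene", "normalized_score", "n_enriched_sgrnas",
                  "n_total_sgrnas") %in% names(ref)),
            n_screens >= 1, baseline >= 1, log2_top > 0)
  n_guides <- sum(ref$n_total_sgrnas)
  spacers <- index_spacers(n_guides)
  guide_id <- unlist(mapply(function(g, k) paste0(g, "_sg", seq_len(k)),
                            ref$gene, ref$n_total_sgrnas, SIMPLIFY = FALSE))
  gene <- rep(ref$gene, ref$n_total_sgrnas)
  lib <- sgrna_library(guide_id, spacers, gene)
  enriched_guide <- unlist(mapply(
    function(k, total) c(rep(TRUE, k), rep(FALSE, total - k)),
    ref$n_enriched_sgrnas, ref$n_total_sgrnas, SIMPLIFY = FALSE))
  target <- rep(round(baseline * 2^(log2_top * ref$normalized_score)),
                ref$n_total_sgrnas)
  survivor <- ifelse(enriched_guide, target, 0L)
  counts <- do.call(rbind, lapply(seq_len(n_screens), function(i) {
    data.frame(screen_id = sprintf("s%d", i),
               guide_id = lib$guide_id,
               baseline_count = as.integer(baseline),
               survivor_count = as.integer(survivor),
               stringsAsFactors = FALSE)
  }))
  list(library = lib, counts = screen_counts(counts, lib))
}

# Deterministic distinct 20-mers: base-4 expansion of 0..(n-1) over ACGT.
index_spacers <- function(n, width = 20L) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n) - 1L, function(i) {
    digits <- integer(width)
    for (p in width:1) {
      digits[p] <- i %% 4L
      i <- i %/% 4L
    }
    paste(bases[digits + 1L], collapse = "")
  }, character(1))
}
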