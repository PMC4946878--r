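# Independent brute-force implementation of the candidate rule, written as
# a literal triple loop over genes, guides and screens. Kept deliberately
# naive (matrix lookups filled row by row, set unions) so it shares no code
# path with the package implementation.

brute_force_calls <- function(counts, library, params) {
  guides <- unique(library$guide_id)
  screens <- unique(counts$screen_id)
  b <- matrix(NA_real_, nrow = length(guides), ncol = length(screens),
              dimnames = list(guides, screens))
  v <- b
  for (i in seq_len(nrow(counts))) {
    b[counts$guide_id[i], counts$screen_id[i]] <- counts$baseline_count[i]
    v[counts$guide_id[i], counts$screen_id[i]] <- counts$survivor_count[i]
  }
  genes <- unique(library$gene)
  res <- data.frame(gene = genes, candidate = FALSE,
                    n_enriched_sgrnas = 0L, n_supporting_screens = 0L,
                    stringsAsFactors = FALSE)
  for (gi in seq_along(genes)) {
    gene_guides <- library$guide_id[library$gene == genes[gi]]
    enriched_guides <- character(0)
    supporting_screens <- character(0)
    for (g in gene_guides) {
      ref <- max(sum(b[g, ]) / length(screens), params$pseudocount)
      for (s in screens) {
        surv <- v[g, s]
        if (surv > params$reads_threshold &&
            surv / ref >= params$fold_threshold) {
          enriched_guides <- union(enriched_guides, g)
          supporting_screens <- union(supporting_screens, s)
        }
      }
    }
    res$n_enriched_sgrnas[gi] <- length(enriched_guides)
    res$n_supporting_screens[gi] <- length(supporting_screens)
    res$candidate[gi] <- length(enriched_guides) >= params$min_sgrnas &&
      length(supporting_screens) >= params$min_screens
  }
  res
}

# Small random experiment with counts concentrated around the rule's
# boundaries (reads near 1000, folds near 3).
random_experiment <- function(seed) {
  set.seed(seed)
  n_genes <- sample(3:50, 1L)
  n_screens <- sample(2:8, 1L)
  gene <- rep(sprintf("G%02d", seq_len(n_genes)), each = 6L)
  guide_id <- paste0(gene, "_", rep(1:6, n_genes))
  lib <- sgrna_library(guide_id, index_spacers_test(length(guide_id)), gene)
  pool <- c(0:5, 50:60, 200:400, 990:1010, 1001, 2900:3100, 5000, 20000)
  counts <- do.call(rbind, lapply(seq_len(n_screens), function(i) {
    data.frame(screen_id = sprintf("s%d", i), guide_id = lib$guide_id,
               baseline_count = sample(c(0:20, 100:400), nrow(lib),
                                       replace = TRUE),
               survivor_count = sample(pool, nrow(lib), replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  list(library = lib, counts = screen_counts(counts, lib))
}

# distinct 20-mers for fixtures (base-4 expansion over ACGT)
index_spacers_test <- function(n) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n) - 1L, function(i) {
    digits <- integer(20L)
    for (p in 20L:1L) {
      digits[p] <- i %% 4L
      i <- i %/% 4L
    }
    paste(bases[digits + 1L], collapse = "")
  }, character(1))
}

# Tiny two-gene library used across I/O and enrichment tests.
toy_library <- function(n_genes = 2L, guides_per_gene = 6L) {
  gene <- rep(sprintf("GENE%d", seq_len(n_genes)), each = guides_per_gene)
  guide_id <- paste0(gene, "_sg", rep(seq_len(guides_per_gene), n_genes))
  sgrna_library(guide_id, index_spacers_test(length(guide_id)), gene)
}

# Hand-assembled enrichment record rows for vote tests.
record_rows <- function(gene, guide_id, screen_id, fold = 10,
                        enriched = TRUE) {
  data.frame(gene = gene, guide_id = guide_id, screen_id = screen_id,
             fold = fold, enriched = enriched, stringsAsFactors = FALSE)
}
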