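test_that("the gene vote needs both the sgRNA and the screen minimum", {
  params <- hit_call_params()
  two_guides_two_screens <- record_rows("G1", c("a", "b"), c("s1", "s4"))
  res <- call_gene(two_guides_two_screens, "G1", params)
  expect_true(res$candidate)
  expect_equal(res$n_enriched_sgrnas, 2L)
  expect_equal(res$n_supporting_screens, 2L)

  one_guide_many_screens <- record_rows("G1", rep("a", 8), sprintf("s%d", 1:8))
  expect_false(call_gene(one_guide_many_screens, "G1", params)$candidate)

  three_guides_one_screen <- record_rows("G1", c("a", "b", "c"), "s1")
  expect_false(call_gene(three_guides_one_screen, "G1", params)$candidate)
  expect_true(call_gene(three_guides_one_screen, "G1",
                        hit_call_params(min_screens = 1))$candidate)
})

test_that("per-guide replication mode only counts individually replicated
           guides", {
  strict <- hit_call_params(per_guide_replication = TRUE)
  # a enriched in s1+s2, b enriched in s1 only
  rec <- rbind(record_rows("G1", c("a", "a"), c("s1", "s2")),
               record_rows("G1", "b", "s1"))
  res <- call_gene(rec, "G1", strict)
  expect_equal(res$n_enriched_sgrnas, 1L)
  expect_false(res$candidate)
  # default gene-level mode accepts the same records
  expect_true(call_gene(rec, "G1", hit_call_params())$candidate)
  # b replicated too -> strict mode accepts
  rec2 <- rbind(rec, record_rows("G1", "b", "s3"))
  expect_true(call_gene(rec2, "G1", strict)$candidate)
})

test_that("ranking is by score, then enriched guides, then symbol", {
  tab <- data.frame(gene = c("B", "A", "C", "D"),
                    normalized_score = c(0.5, 0.5, 1.0, 0.5),
                    n_enriched_sgrnas = c(3L, 2L, 4L, 3L),
                    stringsAsFactors = FALSE)
  ranked <- rank_candidates(tab)
  expect_equal(ranked$gene, c("C", "B", "D", "A"))
})

test_that("all-zero survivor counts yield an empty candidate set", {
  lib <- toy_library(3L)
  df <- expand.grid(screen_id = c("s1", "s2"), guide_id = lib$guide_id,
                    stringsAsFactors = FALSE)
  df$baseline_count <- 100L
  df$survivor_count <- 0L
  fit <- call_candidates(screen_counts(df, lib), lib)
  expect_equal(nrow(fit), 0L)
  expect_equal(sum(fit$candidate), 0L)
})

test_that("stricter thresholds call a subset of looser thresholds", {
  sim <- simulate_screen(simulation_params(n_genes = 30, n_screens = 6,
                                           n_resistance = 4,
                                           spurious_rate = 2, seed = 21,
                                           sequencing_depth = 90000L))
  loose <- call_candidates(sim$counts, sim$library,
                           hit_call_params(min_sgrnas = 1, min_screens = 1))
  for (ms in 1:3) for (mg in 1:3) {
    p <- hit_call_params(min_sgrnas = mg, min_screens = ms)
    strict_set <- call_candidates(sim$counts, sim$library, p)
    expect_true(all(strict_set$gene[strict_set$candidate] %in%
                      loose$gene[loose$candidate]))
  }
})

test_that("removing a screen never increases screen support", {
  sim <- simulate_screen(simulation_params(n_genes = 20, n_screens = 5,
                                           n_resistance = 3,
                                           spurious_rate = 2, seed = 8,
                                           sequencing_depth = 60000L))
  full <- call_candidates(sim$counts, sim$library)
  for (drop in unique(sim$counts$screen_id)) {
    sub <- sim$counts[sim$counts$screen_id != drop, ]
    fit <- call_candidates(screen_counts(sub, sim$library), sim$library)
    shared <- intersect(fit$gene, full$gene)
    expect_true(all(fit$n_supporting_screens[match(shared, fit$gene)] <=
                      full$n_supporting_screens[match(shared, full$gene)]))
  }
})

test_that("hit calls match the brute-force rule on random experiments", {
  params <- hit_call_params()
  for (seed in 1:25) {
    ex <- random_experiment(seed)
    fit <- call_candidates(ex$counts, ex$library, params)
    oracle <- brute_force_calls(ex$counts, ex$library, params)
    merged <- merge(as.data.frame(fit), oracle, by = "gene",
                    suffixes = c("", ".oracle"))
    expect_equal(nrow(merged), nrow(fit))
    expect_equal(merged$candidate, merged$candidate.oracle)
    expect_equal(merged$n_enriched_sgrnas, merged$n_enriched_sgrnas.oracle)
    expect_equal(merged$n_supporting_screens,
                 merged$n_supporting_screens.oracle)
    # genes the oracle finds but the table omits must have no enriched event
    omitted <- setdiff(oracle$gene, fit$gene)
    expect_true(all(oracle$n_enriched_sgrnas[oracle$gene %in% omitted] == 0))
  }
})

test_that("candidate tables print, summarize and export coherently", {
  ref <- reference_candidates()
  sim <- counts_from_candidates(ref)
  fit <- call_candidates(sim$counts, sim$library)
  expect_output(print(fit), "27 candidates")
  expect_output(summary(fit), "Top hit:.*TP53")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_candidates(fit, path)
  out <- read.delim(path, colClasses = "character")
  expect_equal(nrow(out), nrow(fit))
  expect_equal(out$normalized_score[1], "1.0000")
  expect_equal(out$enriched_fraction[out$gene == "P21"], "6/6")
})
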