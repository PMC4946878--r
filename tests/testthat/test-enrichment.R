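make_counts <- function(baselines, survivors, lib = toy_library(1L, 1L)) {
  # one guide observed across length(baselines) screens
  df <- data.frame(screen_id = sprintf("s%d", seq_along(baselines)),
                   guide_id = lib$guide_id[1L],
                   baseline_count = baselines, survivor_count = survivors)
  screen_counts(df, lib)
}

test_that("baseline reference pools, floors and switches modes correctly", {
  params <- hit_call_params()
  tab <- make_counts(c(100, 100, 100, 100), c(0, 0, 0, 0))
  expect_equal(baseline_reference(tab, params), rep(100, 4))

  zero <- make_counts(c(0, 0, 0), c(0, 0, 0))
  expect_equal(baseline_reference(zero, params), rep(1, 3))

  per <- hit_call_params(baseline_mode = "per_guide_per_screen")
  mixed <- make_counts(c(100, 200, 250), c(0, 0, 0))
  expect_equal(baseline_reference(mixed, per), c(100, 200, 250))
  expect_equal(baseline_reference(mixed, params), rep(550 / 3, 3))
})

test_that("the enrichment rule is strict on reads and inclusive on fold", {
  res <- flag_enriched(c(1500, 1000, 5000, 3000), c(400, 1, 2000, 1000))
  expect_equal(res$fold, c(3.75, 1000, 2.5, 3))
  expect_equal(res$enriched, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("gene raw scores are log2 of the mean fold over enriched events", {
  rec <- record_rows("G1", c("a", "a"), c("s1", "s2"), fold = c(4, 16))
  rec <- rbind(rec, record_rows("G2", "b", "s1", fold = 8),
               record_rows("G3", "c", "s1", fold = 99, enriched = FALSE))
  raw <- gene_raw_scores(rec)
  expect_equal(raw$raw_score[raw$gene == "G1"], log2(10))
  expect_equal(raw$raw_score[raw$gene == "G2"], 3.0)
  expect_equal(raw$raw_score[raw$gene == "G3"], 0)
  expect_true(raw$excluded[raw$gene == "G3"])
  expect_false(any(raw$excluded[raw$gene != "G3"]))
})

test_that("normalization maps exactly the argmax set to 1 and stays in
           (0, 1]", {
  norm <- normalize_scores(c(a = 4, b = 2))
  expect_equal(norm, c(a = 1, b = 0.5))

  tie <- normalize_scores(c(a = 3, b = 3, c = 1))
  expect_equal(unname(tie[c("a", "b")]), c(1, 1))
  expect_true(all(tie > 0 & tie <= 1))
  expect_setequal(names(tie)[tie == 1], c("a", "b"))

  expect_warning(empty <- normalize_scores(c(a = 0, b = 0)), "no gene")
  expect_length(empty, 0L)
})

test_that("enrichment monotonicity: more survivor reads never hurt", {
  lib <- toy_library()
  base <- data.frame(screen_id = rep(c("s1", "s2"), each = nrow(lib)),
                     guide_id = rep(lib$guide_id, 2L),
                     baseline_count = 100L, survivor_count = 900L)
  for (surv in c(1200L, 5000L, 50000L)) {
    lower <- base
    higher <- base
    lower$survivor_count[1L] <- surv
    higher$survivor_count[1L] <- surv * 2L
    rl <- enrichment_table(screen_counts(lower, lib), lib)
    rh <- enrichment_table(screen_counts(higher, lib), lib)
    expect_gte(rh$fold[1L], rl$fold[1L])
    expect_gte(rh$enriched[1L], rl$enriched[1L])
    expect_gte(gene_raw_scores(rh)$raw_score[1L],
               gene_raw_scores(rl)$raw_score[1L])
  }
})

test_that("doubling every baseline halves every fold when the pseudocount
           is not binding", {
  sim <- simulate_screen(simulation_params(n_genes = 10, n_screens = 3,
                                           sequencing_depth = 1e5, seed = 4))
  counts <- sim$counts
  counts$baseline_count <- counts$baseline_count + 10L  # keep floor slack
  doubled <- counts
  doubled$baseline_count <- 2L * counts$baseline_count
  r1 <- enrichment_table(screen_counts(counts, sim$library), sim$library)
  r2 <- enrichment_table(screen_counts(doubled, sim$library), sim$library)
  expect_equal(r2$fold, r1$fold / 2)
})

test_that("depth normalization rescales counts to reads per million", {
  lib <- toy_library(1L, 2L)
  df <- data.frame(screen_id = "s1", guide_id = lib$guide_id,
                   baseline_count = c(100L, 300L),
                   survivor_count = c(750L, 250L))
  params <- hit_call_params(depth_normalize = TRUE, reads_threshold = 1e5)
  rec <- enrichment_table(screen_counts(df, lib), lib, params)
  # survivor CPM: 750k and 250k; baseline CPM: 250k and 750k
  expect_equal(rec$fold, c(750000 / 250000, 250000 / 750000))
  expect_equal(rec$enriched, c(TRUE, FALSE))
})
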