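test_that("simulated libraries have the advertised shape", {
  lib <- simulate_library(simulation_params(n_genes = 10, seed = 7))
  expect_equal(nrow(lib), 60L)
  expect_equal(anyDuplicated(lib$spacer), 0L)
  expect_true(all(nchar(lib$spacer) == 20L))
  expect_true(all(table(lib$gene) == 6L))
  # six guides per gene is the library design default
  expect_equal(simulation_params()$sgrnas_per_gene, 6L)
  expect_error(simulation_params(n_genes = 0), "n_genes")
})

test_that("identical parameters and seed give byte-identical output", {
  p <- simulation_params(n_genes = 8, n_screens = 3,
                         sequencing_depth = 10000, seed = 11)
  expect_identical(simulate_library(p), simulate_library(p))
  a <- simulate_screen(p)
  b <- simulate_screen(p)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
})

test_that("adding screens never perturbs earlier screens", {
  p4 <- simulation_params(n_genes = 6, n_screens = 4,
                          sequencing_depth = 20000, seed = 5)
  p8 <- simulation_params(n_genes = 6, n_screens = 8,
                          sequencing_depth = 20000, seed = 5)
  lib <- simulate_library(p4)
  t4 <- simulate_truth(lib, p4)
  t8 <- simulate_truth(lib, p8)
  c4 <- simulate_counts(lib, t4, p4)
  c8 <- simulate_counts(lib, t8, p8)
  first4 <- c8[c8$screen_id %in% sprintf("s%d", 1:4), ]
  expect_equal(as.data.frame(first4), as.data.frame(c4))
})

test_that("truth planting honours counts, efficacy model and bounds", {
  p <- simulation_params(n_genes = 100, n_resistance = 5,
                         efficacy_model = "constant(1)", seed = 2)
  lib <- simulate_library(p)
  truth <- simulate_truth(lib, p)
  expect_length(truth$resistance_genes, 5L)
  expect_length(truth$guide_efficacy, 30L)
  expect_true(all(truth$guide_efficacy == 1))

  empty <- simulate_truth(lib, p, n_resistance = 0)
  expect_length(empty$resistance_genes, 0L)

  expect_error(simulate_truth(lib, p, n_resistance = 101), "exceeds")
  expect_error(simulation_params(efficacy_model = "uniform(0,1)"),
               "efficacy model")
})

test_that("bernoulli efficacy gives the expected mean effective guides", {
  # Binomial(6, 2/3) per gene: mean effective guides 4. Monte Carlo across
  # seeds; 3-standard-error band.
  p <- simulation_params(n_genes = 10, n_resistance = 10,
                         efficacy_model = "bernoulli(0.6666667)")
  lib <- simulate_library(p)
  eff <- unlist(lapply(1:120, function(s)
    simulate_truth(lib, p, seed = s)$guide_efficacy))
  n_genes_total <- length(eff) / 6
  expect_gt(n_genes_total, 1000 / 6)
  per_gene_mean <- 6 * mean(eff)
  se <- sqrt(6 * (2 / 3) * (1 / 3) / n_genes_total)
  expect_lt(abs(per_gene_mean - 4), 3 * se)
})

test_that("survivor counts are conserved at sequencing depth", {
  sim <- simulate_screen(simulation_params(n_genes = 12, n_screens = 5,
                                           sequencing_depth = 44321,
                                           seed = 9))
  sums <- tapply(sim$counts$survivor_count, sim$counts$screen_id, sum)
  expect_true(all(sums == 44321L))
  expect_true(all(sim$counts$baseline_count >= 0))
})

test_that("strong selection drives every effective resistance guide over
           both thresholds", {
  p <- strong_selection_params(seed = 42)
  sim <- simulate_screen(p)
  res_guides <- names(sim$truth$guide_efficacy)
  rows <- sim$counts[sim$counts$guide_id %in% res_guides, ]
  base_mean <- tapply(sim$counts$baseline_count, sim$counts$guide_id, mean)
  expect_true(all(rows$survivor_count > 1000))
  expect_true(all(rows$survivor_count >=
                    3 * base_mean[rows$guide_id]))
})

test_that("without spurious events, non-resistance guides do not enrich on
           average", {
  p <- strong_selection_params(seed = 7)
  p$spurious_rate <- 0
  sim <- simulate_screen(p)
  records <- enrichment_table(sim$counts, sim$library)
  non_res <- !(records$gene %in% sim$truth$resistance_genes)
  folds <- records$fold[non_res]
  expect_lt(mean(folds) + 3 * sd(folds) / sqrt(length(folds)), 1)
})

test_that("raising the selection advantage raises expected survivor counts
           of effective resistance guides", {
  mean_res_count <- function(s, seeds) {
    vals <- vapply(seeds, function(seed) {
      p <- simulation_params(n_genes = 20, n_screens = 1,
                             n_resistance = 2, efficacy_model = "constant(1)",
                             selection_advantage = s, spurious_rate = 0,
                             sequencing_depth = 60000, seed = seed)
      sim <- simulate_screen(p)
      rows <- sim$counts$guide_id %in% names(sim$truth$guide_efficacy)
      mean(sim$counts$survivor_count[rows])
    }, numeric(1))
    mean(vals)
  }
  seeds <- 1:60
  expect_gt(mean_res_count(20, seeds), mean_res_count(2, seeds))
})

test_that("no selection and no artifacts yield zero candidates end to end", {
  p <- strong_selection_params(seed = 13)
  p$selection_advantage <- 1
  p$spurious_rate <- 0
  # survivor depth matched to baseline total: nothing expands
  p$sequencing_depth <- p$n_genes * p$sgrnas_per_gene * p$baseline_mean
  sim <- simulate_screen(p)
  fit <- call_candidates(sim$counts, sim$library)
  expect_equal(sum(fit$candidate), 0L)
})
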