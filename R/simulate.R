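#' Simulation parameters for a synthetic positive-selection screen
#'
#' Describes a pooled knockout survival screen: a library of `n_genes` genes
#' with `sgrnas_per_gene` guides each is screened in `n_screens` independent
#' screens. Baseline counts follow a negative binomial (gamma-Poisson) with
#' mean `baseline_mean` and overdispersion `dispersion`. During selection,
#' cells carrying an effective knockout of one of `n_resistance` planted
#' resistance genes expand `selection_advantage`-fold relative to the
#' arrested background, whose abundance shrinks by `depletion`; per-guide
#' knockout efficacy is drawn from `efficacy_model`. Each screen suffers, on
#' average, `spurious_rate` off-target/passenger artifacts: uniformly chosen
#' guides whose abundance is inflated `spurious_inflation`-fold in that one
#' screen. Survivor pools are resequenced to a fixed `sequencing_depth` by
#' multinomial resampling.
#'
#' @param n_genes Number of genes in the library.
#' @param sgrnas_per_gene Guides per gene (libraries of this design carry at
#'   least six).
#' @param n_screens Number of independent screens.
#' @param baseline_mean Expected baseline reads per guide.
#' @param dispersion Negative-binomial overdispersion of baseline abundance
#'   (0 gives pure Poisson).
#' @param sequencing_depth Total survivor reads per screen.
#' @param spurious_rate Expected spuriously inflated guides per screen.
#' @param spurious_inflation Abundance multiplier of a spurious event.
#' @param depletion Relative abundance factor of arrested (non-rescued)
#'   cells after the selection period.
#' @param n_resistance Number of planted resistance genes.
#' @param efficacy_model Per-guide knockout efficacy for resistance-gene
#'   guides: `"constant(x)"`, `"bernoulli(p)"` or `"beta(a,b)"`.
#' @param selection_advantage Fold expansion (>= 1) of cells carrying an
#'   effective resistance knockout, relative to their own arrested fate.
#' @param seed Master seed; every draw in the simulation is a deterministic
#'   function of it.
#'
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_genes = 100L,
                              sgrnas_per_gene = 6L,
                              n_screens = 8L,
                              baseline_mean = 500,
                              dispersion = 0.3,
                              sequencing_depth = 1e6,
                              spurious_rate = 1,
                              spurious_inflation = 100,
                              depletion = 0.05,
                              n_resistance = 5L,
                              efficacy_model = "bernoulli(0.7)",
                              selection_advantage = 50,
                              seed = 1L) {
  stopifnot(n_genes >= 1, sgrnas_per_gene >= 1, n_screens >= 1,
            baseline_mean > 0, dispersion >= 0, sequencing_depth >= 1,
            spurious_rate >= 0, spurious_inflation > 0, depletion > 0,
            n_resistance >= 0, n_resistance <= n_genes,
            selection_advantage >= 1)
  parse_efficacy_model(efficacy_model)  # fail fast on a bad model string
  out <- list(n_genes = as.integer(n_genes),
              sgrnas_per_gene = as.integer(sgrnas_per_gene),
              n_screens = as.integer(n_screens),
              baseline_mean = baseline_mean,
              dispersion = dispersion,
              sequencing_depth = as.integer(sequencing_depth),
              spurious_rate = spurious_rate,
              spurious_inflation = spurious_inflation,
              depletion = depletion,
              n_resistance = as.integer(n_resistance),
              efficacy_model = efficacy_model,
              selection_advantage = selection_advantage,
              seed = as.integer(seed))
  class(out) <- "simulation_params"
  out
}

#' Strong-selection benchmark preset
#'
#' The canonical recovery benchmark: 100 genes x 6 guides in 8 independent
#' screens, 5 planted resistance genes with fully effective guides
#' (`constant(1)`), a 50-fold selection advantage, one spurious artifact per
#' screen, baseline mean 500 reads and survivor depth 1e6. Under these
#' conditions the candidate rule should recover all planted genes with no
#' false positives.
#'
#' @param seed Master seed.
#' @return A `simulation_params` object.
#' @export
strong_selection_params <- function(seed = 42L) {
  simulation_params(n_genes = 100L, sgrnas_per_gene = 6L, n_screens = 8L,
                    baseline_mean = 500, dispersion = 0.3,
                    sequencing_depth = 1e6, spurious_rate = 1,
                    spurious_inflation = 100, depletion = 0.05,
                    n_resistance = 5L, efficacy_model = "constant(1)",
                    selection_advantage = 50, seed = seed)
}

#' Null-screen preset (no planted resistance genes)
#'
#' Conditions for studying false positives caused purely by spurious
#' artifacts: no planted genes, so nothing truly expands. The survivor
#' sample is sequenced to a depth matched to the baseline total
#' (`n_guides * baseline_mean`); with no expanding clones, sequencing far
#' deeper than the baseline total would inflate every guide's fold by
#' roughly `depth / (n_guides * baseline_mean)` and swamp the artifact
#' signal this preset is meant to isolate.
#'
#' @param seed Master seed.
#' @param spurious_rate Expected spurious guides per screen.
#' @return A `simulation_params` object.
#' @export
null_screen_params <- function(seed = 42L, spurious_rate = 2) {
  simulation_params(n_genes = 100L, sgrnas_per_gene = 6L, n_screens = 8L,
                    baseline_mean = 500, dispersion = 0.3,
                    sequencing_depth = 100L * 6L * 500L,
                    spurious_rate = spurious_rate,
                    spurious_inflation = 100, depletion = 0.05,
                    n_resistance = 0L, efficacy_model = "constant(1)",
                    selection_advantage = 50, seed = seed)
}

#' @export
print.simulation_params <- function(x, ...) {
  cat("Screen simulation:", x$n_genes, "genes x", x$sgrnas_per_gene,
      "sgRNAs,", x$n_screens, "screens\n")
  cat("  baseline: NB(mean", x$baseline_mean, ", dispersion",
      x$dispersion, "); survivor depth", x$sequencing_depth, "\n")
  cat("  selection:", x$n_resistance, "resistance genes, advantage",
      x$selection_advantage, "x, efficacy", x$efficacy_model,
      ", depletion", x$depletion, "\n")
  cat("  artifacts:", x$spurious_rate, "spurious guides/screen, inflation",
      x$spurious_inflation, "x; seed", x$seed, "\n")
  invisible(x)
}

# "constant(x)" / "bernoulli(p)" / "beta(a,b)" -> function(n) efficacy draws
parse_efficacy_model <- function(model) {
  m <- regmatches(model, regexec(
    "^\\s*(constant|bernoulli|beta)\\s*\\(([^)]*)\\)\\s*$", model))[[1]]
  if (length(m) == 0L)
    stop("invalid efficacy model: '", model,
         "' (use constant(x), bernoulli(p) or beta(a,b))")
  args <- suppressWarnings(as.numeric(strsplit(m[3], ",")[[1]]))
  if (anyNA(args)) stop("invalid efficacy model arguments in '", model, "'")
  switch(m[2],
    constant = {
      if (length(args) != 1L || args < 0 || args > 1)
        stop("constant efficacy must be one value in [0,1]")
      function(n) rep(args, n)
    },
    bernoulli = {
      if (length(args) != 1L || args < 0 || args > 1)
        stop("bernoulli efficacy needs one probability in [0,1]")
      function(n) as.numeric(rbinom(n, 1L, args))
    },
    beta = {
      if (length(args) != 2L || any(args <= 0))
        stop("beta efficacy needs two positive shape parameters")
      function(n) rbeta(n, args[1], args[2])
    })
}

#' Simulate an sgRNA library
#'
#' Generates `n_genes * sgrnas_per_gene` guides with distinct random 20-nt
#' ACGT spacers and synthetic gene symbols (`GENE001`, ...). Fully
#' reproducible from `params$seed`.
#'
#' @param params A [simulation_params()] object.
#' @return An `sgrna_library`.
#' @export
simulate_library <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  n <- params$n_genes * params$sgrnas_per_gene
  gene <- rep(sprintf("GENE%03d", seq_len(params$n_genes)),
              each = params$sgrnas_per_gene)
  guide_id <- paste0(gene, "_sg",
                     rep(seq_len(params$sgrnas_per_gene), params$n_genes))
  spacer <- with_rng_state(rng_stream_state(params$seed, 1L),
                           random_spacers(n))
  sgrna_library(guide_id, spacer, gene)
}

random_spacers <- function(n, width = 20L) {
  bases <- c("A", "C", "G", "T")
  draw <- function(k) {
    m <- matrix(sample(bases, k * width, replace = TRUE), nrow = k)
    apply(m, 1L, paste, collapse = "")
  }
  spacers <- draw(n)
  while (anyDuplicated(spacers)) {   # collisions are ~never at 4^20 space
    dup <- duplicated(spacers)
    spacers[dup] <- draw(sum(dup))
  }
  spacers
}

#' Simulate screen ground truth
#'
#' Plants `n_resistance` resistance genes (knockouts that rescue
#' proliferation under selection, the TP53/53BP1/USP28/p21 analogues),
#' draws a knockout efficacy for each of their guides from
#' `efficacy_model`, and pre-draws the spurious artifact events for every
#' screen: a Poisson(`spurious_rate`) number of uniformly chosen guides per
#' screen, each to be inflated `spurious_inflation`-fold in that screen
#' only.
#'
#' @param library An `sgrna_library`.
#' @param params A [simulation_params()] object.
#' @param n_resistance,efficacy_model,selection_advantage Overrides of the
#'   corresponding `params` fields.
#' @param seed Override of `params$seed`.
#' @return An object of class `simulation_truth`: a list with
#'   `resistance_genes` (character), `guide_efficacy` (named numeric over
#'   the resistance genes' guides), `selection_advantage`, and
#'   `spurious_events` (data frame `screen_id`, `guide_id`,
#'   `inflation_factor`).
#' @export
simulate_truth <- function(library, params,
                           n_resistance = params$n_resistance,
                           efficacy_model = params$efficacy_model,
                           selection_advantage = params$selection_advantage,
                           seed = params$seed) {
  stopifnot(inherits(library, "sgrna_library"),
            inherits(params, "simulation_params"))
  genes <- unique(library$gene)
  if (n_resistance > length(genes))
    stop("n_resistance (", n_resistance, ") exceeds number of genes (",
         length(genes), ")")
  eff_fun <- parse_efficacy_model(efficacy_model)
  with_rng_state(rng_stream_state(seed, 2L), {
    resistance <- if (n_resistance > 0L) sort(sample(genes, n_resistance))
                  else character(0)
    res_guides <- library$guide_id[library$gene %in% resistance]
    efficacy <- setNames(eff_fun(length(res_guides)), res_guides)
    events <- lapply(seq_len(params$n_screens), function(i) {
      k <- rpois(1L, params$spurious_rate)
      if (k == 0L) return(NULL)
      data.frame(screen_id = sprintf("s%d", i),
                 guide_id = sample(library$guide_id, k),
                 inflation_factor = params$spurious_inflation,
                 stringsAsFactors = FALSE)
    })
    events <- if (all(vapply(events, is.null, logical(1))))
      data.frame(screen_id = character(0), guide_id = character(0),
                 inflation_factor = numeric(0), stringsAsFactors = FALSE)
    else do.call(rbind, events)
    structure(list(resistance_genes = resistance,
                   guide_efficacy = efficacy,
                   selection_advantage = selection_advantage,
                   spurious_events = events),
              class = "simulation_truth")
  })
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("Simulation truth:", length(x$resistance_genes),
      "resistance genes (advantage", x$selection_advantage, "x),",
      nrow(x$spurious_events), "spurious events\n")
  if (length(x$resistance_genes))
    cat("  genes:", paste(x$resistance_genes, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate screen count tables
#'
#' Each guide's latent abundance — its representation in the pooled
#' lentiviral library, shared by all screens infected from that pool — is
#' drawn once from a gamma with mean `baseline_mean` and variance
#' `dispersion * mean^2`. Each screen (an independent RNG substream of the
#' master seed, so adding screens never changes earlier ones) then draws
#' its baseline sample Poisson around that abundance (together,
#' negative-binomial baseline counts). Selection multiplies each
#' guide's abundance by `depletion * (1 + efficacy * (advantage - 1))`
#' (efficacy 0 for all non-resistance guides), so an effective resistance
#' knockout ends up `advantage`-fold above the arrested background while
#' `advantage = 1` is exactly neutral. The screen's spurious events from
#' `truth` then inflate their guides, and the survivor sample is a
#' multinomial of size `sequencing_depth` over the final abundances (counts
#' sum exactly to the depth).
#'
#' @param library An `sgrna_library`.
#' @param truth A `simulation_truth` from [simulate_truth()].
#' @param params A [simulation_params()] object.
#' @return A `screen_counts` table covering all screens.
#' @export
simulate_counts <- function(library, truth, params) {
  stopifnot(inherits(library, "sgrna_library"),
            inherits(truth, "simulation_truth"),
            inherits(params, "simulation_params"))
  unknown <- setdiff(c(names(truth$guide_efficacy),
                       truth$spurious_events$guide_id), library$guide_id)
  if (length(unknown))
    stop("truth references guides absent from library: ",
         paste(unknown, collapse = ", "))
  n <- nrow(library)
  eff <- setNames(numeric(n), library$guide_id)
  eff[names(truth$guide_efficacy)] <- truth$guide_efficacy
  s <- truth$selection_advantage
  rel <- params$depletion * (1 + eff * (s - 1))
  lambda <- with_rng_state(rng_stream_state(params$seed, 3L), {
    if (params$dispersion > 0)
      rgamma(n, shape = 1 / params$dispersion,
             scale = params$baseline_mean * params$dispersion)
    else rep(params$baseline_mean, n)
  })
  per_screen <- lapply(seq_len(params$n_screens), function(i) {
    sid <- sprintf("s%d", i)
    with_rng_state(rng_stream_state(params$seed, 3L + i), {
      baseline <- rpois(n, lambda)
      rel_i <- rel
      ev <- truth$spurious_events[truth$spurious_events$screen_id == sid, ]
      if (nrow(ev)) {
        idx <- match(ev$guide_id, library$guide_id)
        rel_i[idx] <- rel_i[idx] * ev$inflation_factor
      }
      abundance <- lambda * rel_i
      survivor <- as.integer(
        rmultinom(1L, size = params$sequencing_depth, prob = abundance))
      data.frame(screen_id = sid, guide_id = library$guide_id,
                 baseline_count = baseline, survivor_count = survivor,
                 stringsAsFactors = FALSE)
    })
  })
  screen_counts(do.call(rbind, per_screen), library)
}

#' Simulate a complete screen experiment
#'
#' Convenience wrapper chaining [simulate_library()], [simulate_truth()]
#' and [simulate_counts()].
#'
#' @param params A [simulation_params()] object.
#' @return A list of class `screen_simulation` with elements `library`,
#'   `truth`, `counts`, `params`.
#' @examples
#' sim <- simulate_screen(strong_selection_params(seed = 42))
#' @export
simulate_screen <- function(params) {
  library <- simulate_library(params)
  truth <- simulate_truth(library, params)
  counts <- simulate_counts(library, truth, params)
  structure(list(library = library, truth = truth, counts = counts,
                 params = params),
            class = "screen_simulation")
}

#' @export
print.screen_simulation <- function(x, ...) {
  print(x$params)
  print(x$truth)
  invisible(x)
}
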