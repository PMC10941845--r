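# Shared, lazily-built fixtures. Cohort generation is the expensive part
# of the suite, so each fixture is computed once per test run and reused.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env, inherits = FALSE)
}

# Small cohort for structural tests (patches, I/O, encoder).
tiny_cohort <- function() {
  memo("tiny", function() generate_cohort(cohort_config(n_per_stage = 2, seed = 101)))
}

# 20-per-stage cohort with features and anomaly stage: the default study
# conditions for the anomaly and mixed-model checks.
mid_cohort <- function() {
  memo("mid", function() {
    cohort <- generate_cohort(cohort_config(n_per_stage = 20, seed = 202))
    features <- embed_cohort(cohort, d = 128L)
    anomaly <- anomaly_stage(features, k_range = 1:3, whiten_dims = 16L,
                             seed = 11)
    prm <- prm_cohort_table(cohort)
    list(cohort = cohort, features = features, anomaly = anomaly, prm = prm)
  })
}

# 30-per-stage cohort and its PRM table for calibration checks.
calib_cohort <- function() {
  memo("calib", function() {
    cohort <- generate_cohort(cohort_config(n_per_stage = 30, seed = 303))
    list(cohort = cohort, prm = prm_cohort_table(cohort))
  })
}

# Patch records drawn directly from the per-class HU models: whole-patch
# lesion or whole-patch normal tissue, for class-separation checks.
pure_class_patches <- function(n_each = 40, side = 24L, seed = 71) {
  memo(sprintf("pure_%d_%d_%d", n_each, side, seed), function() {
    hu <- default_hu_models()
    draw <- function(m, n) {
      array(qnorm(runif(n, pnorm(m$lower, m$mean, m$sd), pnorm(m$upper, m$mean, m$sd)),
                  m$mean, m$sd), dim = c(side, side, side))
    }
    withr::with_seed(seed, {
      mk <- function(cls) {
        lapply(seq_len(n_each), function(i) {
          list(insp = draw(hu[[cls]]$insp, side^3),
               exp = draw(hu[[cls]]$exp, side^3),
               mask = array(TRUE, dim = c(side, side, side)),
               origin = c(0L, 0L, 0L))
        })
      }
      list(normal = mk("normal"), emph = mk("emph"))
    })
  })
}

# Independent adjusted-Rand-index oracle used to score cluster recovery.
rand_index_adjusted <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maximum <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maximum - expected)
}
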