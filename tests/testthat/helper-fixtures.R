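# Shared simulated populations, built once per test run. The seed is a
# fixed constant (study enrolment start date) chosen before any result was
# inspected.
.fixture_cache <- new.env(parent = emptyenv())

fixture_seed <- 20190411L

pop50k <- function() {
  if (is.null(.fixture_cache$pop50k)) {
    .fixture_cache$pop50k <- make_hhcy_population(50000, seed = fixture_seed)
  }
  .fixture_cache$pop50k
}

pop20k <- function() {
  if (is.null(.fixture_cache$pop20k)) {
    .fixture_cache$pop20k <- make_hhcy_population(20000, seed = fixture_seed)
  }
  .fixture_cache$pop20k
}

# v-structure fixture: X and Y independent coins, Z depends strongly on
# both (noisy AND is enough to induce both edges at this n).
vstructure_dataset <- function(n = 20000, seed = 11) {
  set.seed(seed)
  x <- stats::rbinom(n, 1, 0.5)
  y <- stats::rbinom(n, 1, 0.5)
  pz <- 0.05 + 0.55 * x + 0.35 * y
  z <- stats::rbinom(n, 1, pz)
  tibble::tibble(X = factor(x, 0:1), Y = factor(y, 0:1),
                 Z = factor(z, 0:1))
}
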