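# Shared synthetic-study fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# Small study for unit-level pipeline tests (72 ROIs / session).
small_study <- function() {
  cached("small_study", function() {
    generate_study(dataset_spec(n_patients = 6, seed = 101))
  })
}

# Tiny two-sequence study for orchestration tests.
tiny_study <- function() {
  cached("tiny_study", function() {
    generate_study(dataset_spec(n_patients = 5, regions_per_patient = 1,
                                n_sequences = 2, seed = 202))
  })
}

# Default-scale study emulating the full reading design (444 ROIs/session).
default_study <- function() {
  cached("default_study", function() {
    generate_study(dataset_spec(seed = 303))
  })
}

disk_mask <- function(n = 128, radius = 30) {
  ellipse_mask(n, n, c(n / 2, n / 2), c(radius, radius))
}
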