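# Shared fixtures, built in code. Heavy objects are cached per test run.

.tmf_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .tmf_cache)) {
    assign(key, force(expr), envir = .tmf_cache)
  }
  get(key, envir = .tmf_cache)
}

# small world: 2-helix bundles, 10-residue membrane segments, thin slab
mini_spec <- function(...) {
  fixture_spec(
    n_fold_classes = 2L, helices_per_bundle = 2L, helix_length = 10L,
    tail_length = 2L, membrane_half_thickness = 8, rng_seed = 11L, ...
  )
}

mini_bundle <- function(class_index = 1L, ...) {
  make_bundle(mini_spec(...), class_index)
}

default_library <- function() {
  cached("default_library", make_library(fixture_spec(), queries_per_class = 8L))
}

# hand-built chain: residues on a line along x at z = 0, all labelled M,
# explicit coordinates so contact distances are exact
line_structure <- function(aa, x, z = rep(0, length(x)), half = 15,
                           topology = NULL, symmetry_ops = list(),
                           neighbor_centers = NULL) {
  n <- length(x)
  if (is.null(topology)) topology <- paste(rep("M", n), collapse = "")
  chain_structure(
    chain_id = "toy",
    residues = tibble::tibble(
      index = seq_len(n) - 1L, aa = aa,
      x = x, y = rep(0, n), z = z
    ),
    topology = topology,
    symmetry_ops = symmetry_ops,
    half_thickness = half,
    neighbor_centers = neighbor_centers
  )
}

random_potential <- function(seed = 5L, sd_pair = 1, sd_lipid = 0.2) {
  set.seed(seed)
  m <- matrix(rnorm(400, sd = sd_pair), 20, 20)
  potential_set((m + t(m)) / 2, rnorm(20, sd = sd_lipid))
}

random_region_string <- function(n_m, with_r = FALSE) {
  sides <- c("1", "2", if (with_r) "R")
  toks <- character(2 * n_m + 1)
  toks[seq(2, 2 * n_m, by = 2)] <- "M"
  for (i in seq(1, 2 * n_m + 1, by = 2)) toks[i] <- sample(sides, 1)
  paste(rep(toks, times = sample(1:4, length(toks), replace = TRUE)),
        collapse = "")
}
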