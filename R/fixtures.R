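#' Specification of a synthetic fixture library
#'
#' Describes a toy world of alpha-helical bundle templates with known
#' ground truth: fold classes differ by the 2D packing arrangement of
#' their helix axes, sequences are sampled from a known potential, and
#' everything is deterministic under the seed. Defaults: 4 fold classes
#' of 3-helix bundles, 20-residue membrane segments, 15 Angstrom
#' half thickness.
#'
#' @param n_fold_classes number of fold classes (1..6).
#' @param helices_per_bundle helices (= membrane segments, NTM) per chain.
#' @param helix_length membrane-embedded residues per helix.
#' @param inter_helix_distance axis-to-axis spacing in Angstrom.
#' @param membrane_half_thickness slab half thickness in Angstrom.
#' @param tail_length residues extending beyond the slab on each helix
#'   end (they carry the side labels).
#' @param sampling_temperature Metropolis temperature at which native and
#'   query sequences are drawn from the ground-truth potential. The low
#'   default (0.3) emulates sequences strongly optimized for their own
#'   fold, the regime fold recognition assumes.
#' @param ground_truth_potential `tmf_potential` used to sample
#'   sequences; default: a seeded random potential from
#'   [make_ground_truth_potential()].
#' @param rng_seed master seed; all per-item seeds derive from it.
#' @return A `tmf_fixture_spec` list.
#' @export
fixture_spec <- function(n_fold_classes = 4L,
                         helices_per_bundle = 3L,
                         helix_length = 20L,
                         inter_helix_distance = 9.5,
                         membrane_half_thickness = 15,
                         tail_length = 4L,
                         sampling_temperature = 0.3,
                         ground_truth_potential = NULL,
                         rng_seed = 42L) {
  stopifnot(n_fold_classes >= 1L, n_fold_classes <= 6L,
            helices_per_bundle >= 1L, helix_length >= 8L)
  if (is.null(ground_truth_potential)) {
    ground_truth_potential <- make_ground_truth_potential(rng_seed)
  }
  structure(
    list(
      n_fold_classes = as.integer(n_fold_classes),
      helices_per_bundle = as.integer(helices_per_bundle),
      helix_length = as.integer(helix_length),
      inter_helix_distance = inter_helix_distance,
      membrane_half_thickness = membrane_half_thickness,
      tail_length = as.integer(tail_length),
      sampling_temperature = sampling_temperature,
      ground_truth_potential = ground_truth_potential,
      rng_seed = as.integer(rng_seed)
    ),
    class = "tmf_fixture_spec"
  )
}

#' Seeded random ground-truth potential
#'
#' Pair energies ~ N(0, 1) (symmetrized), lipid energies ~ N(0, 0.1):
#' lipid terms an order of magnitude smaller than pair terms, matching
#' the relative weight observed in membrane statistical potentials.
#'
#' @param seed integer seed.
#' @return A `tmf_potential`.
#' @export
make_ground_truth_potential <- function(seed = 42L) {
  withr_seed(seed, {
    m <- matrix(stats::rnorm(N_AA * N_AA), N_AA, N_AA)
    eps <- (m + t(m)) / 2
    h <- stats::rnorm(N_AA, sd = 0.1)
    potential_set(eps, h)
  })
}

# xy positions of the helix axes per fold class: distinct adjacency
# patterns so contact maps differ between classes
class_layout <- function(class_index, ntm, d) {
  s3 <- sqrt(3) / 2
  layouts <- list(
    function(i) c((i - 1) * d, 0),                               # linear chain
    function(i) {                                                # triangular lattice
      pts <- rbind(c(0, 0), c(d, 0), c(d / 2, d * s3),
                   c(3 * d / 2, d * s3), c(2 * d, 0), c(d, 2 * d * s3))
      pts[i, ]
    },
    function(i) {                                                # permuted line
      ord <- c(0, 2, 1, 3, 5, 4)
      c(ord[i] * d, 0)
    },
    function(i) {                                                # hub and spokes
      if (i == 1L) return(c(0, 0))
      ang <- 2 * pi * (i - 2) / 2.5
      c(d * cos(ang), d * sin(ang))
    },
    function(i) {                                                # right-angle bend
      pts <- rbind(c(0, 0), c(d, 0), c(d, d), c(d, 2 * d),
                   c(0, 2 * d), c(0, d))
      pts[i, ]
    },
    function(i) {                                                # wide zigzag
      c((i - 1) * d * 0.9, (i %% 2) * d * 1.1)
    }
  )
  t(vapply(seq_len(ntm), layouts[[class_index]], numeric(2)))
}

#' Build one synthetic helical-bundle template
#'
#' Ideal alpha-helices (1.5 Angstrom rise and 100 degrees rotation per
#' residue; C-alpha at 2.3 and C-beta at 3.4 Angstrom from the axis) are
#' placed on the fold class's 2D arrangement, spanning the membrane slab
#' and alternating up/down. Region labels derive from the interaction
#' center z: `M` inside the slab (boundary inclusive), side `1` below,
#' side `2` above.
#'
#' @param spec a [fixture_spec()].
#' @param class_index fold class (1-based).
#' @param chain_id template identifier (default `class<k>`).
#' @param sequence optional amino-acid string; default poly-alanine
#'   placeholder (replace via [sample_sequence()]).
#' @return A `tmf_structure`.
#' @export
make_bundle <- function(spec, class_index, chain_id = NULL, sequence = NULL) {
  ntm <- spec$helices_per_bundle
  n_per <- spec$helix_length + 2L * spec$tail_length
  half <- spec$membrane_half_thickness
  rise <- 1.5
  twist <- 100 * pi / 180
  z0 <- (n_per - 1) * rise / 2
  if (z0 <= half) abort("degenerate geometry: helix does not span the slab")
  centers <- class_layout(class_index, ntm, spec$inter_helix_distance)
  res <- list()
  atoms <- list()
  idx <- 0L
  for (hx in seq_len(ntm)) {
    up <- hx %% 2L == 1L
    for (k in 0:(n_per - 1L)) {
      z <- -z0 + k * rise
      if (!up) z <- -z
      ang <- k * twist + (hx - 1) * 0.7
      ca <- c(centers[hx, 1] + 2.3 * cos(ang), centers[hx, 2] + 2.3 * sin(ang), z)
      cb <- c(centers[hx, 1] + 3.4 * cos(ang), centers[hx, 2] + 3.4 * sin(ang), z)
      res[[idx + 1L]] <- tibble(index = idx, aa = "A",
                                x = cb[1], y = cb[2], z = cb[3])
      atoms[[idx + 1L]] <- tibble(
        res_index = idx, name = c("CA", "CB"),
        x = c(ca[1], cb[1]), y = c(ca[2], cb[2]), z = c(ca[3], cb[3])
      )
      idx <- idx + 1L
    }
  }
  residues <- bind_rows(res)
  atoms <- bind_rows(atoms)
  if (!is.null(sequence)) {
    aa <- seq_chars(sequence)
    if (length(aa) != nrow(residues)) abort("sequence length mismatch")
    residues$aa <- aa
  }
  # glycine has no C-beta: its interaction center is the C-alpha, and the
  # CB pseudo-atom is dropped so files round-trip exactly
  gly <- residues$aa == "G"
  if (any(gly)) {
    ca <- atoms[atoms$name == "CA", ]
    residues$x[gly] <- ca$x[gly]
    residues$y[gly] <- ca$y[gly]
    residues$z[gly] <- ca$z[gly]
    atoms <- atoms[!(atoms$name == "CB" & atoms$res_index %in% residues$index[gly]), ]
  }
  topo <- ifelse(abs(residues$z) <= half, "M",
                 ifelse(residues$z < 0, "1", "2"))
  chain_structure(
    chain_id = chain_id %||% paste0("class", class_index),
    residues = residues,
    atoms = atoms,
    topology = paste(topo, collapse = ""),
    half_thickness = half
  )
}

#' Sample a sequence on a structure by Metropolis annealing
#'
#' Starting from a uniform random sequence, single-position substitutions
#' are proposed uniformly and accepted with the Metropolis rule on the
#' single-sequence threading energy under `potential` at `temperature`.
#' With a zero potential every proposal is accepted and the result is a
#' uniform random sequence. Deterministic given the seed.
#'
#' @param structure a `tmf_structure`.
#' @param potential the ground-truth `tmf_potential`.
#' @param temperature Metropolis temperature, > 0 (energy units).
#' @param seed integer seed.
#' @param sweeps proposal sweeps (each sweep = one proposal per residue).
#' @return Amino-acid string of the structure's length.
#' @export
sample_sequence <- function(structure, potential, temperature = 1,
                            seed = 1L, sweeps = 150L) {
  if (temperature <= 0) abort("temperature must be positive")
  geom <- structure_contact_geometry(structure)
  n <- nrow(structure$residues)
  # adjacency: contacts touching each position
  nb <- vector("list", n)
  for (r in seq_along(geom$pair_a)) {
    a <- geom$pair_a[r]; b <- geom$pair_b[r]
    nb[[a]] <- c(nb[[a]], b)
    if (b != a) nb[[b]] <- c(nb[[b]], a)
  }
  is_lipid <- logical(n)
  is_lipid[geom$lipid] <- TRUE
  eps <- potential$epsilon
  h <- potential$h
  withr_seed(seed, {
    ai <- sample.int(N_AA, n, replace = TRUE)
    n_prop <- sweeps * n
    pos <- sample.int(n, n_prop, replace = TRUE)
    prop <- sample.int(N_AA, n_prop, replace = TRUE)
    u <- runif(n_prop)
    for (t in seq_len(n_prop)) {
      p <- pos[t]
      new <- prop[t]
      old <- ai[p]
      if (new == old) next
      q <- nb[[p]]
      de <- 0
      if (length(q) > 0L) {
        de <- sum(eps[new, ai[q]]) - sum(eps[old, ai[q]])
      }
      if (is_lipid[p]) de <- de + h[new] - h[old]
      if (de <= 0 || u[t] < exp(-de / temperature)) ai[p] <- new
    }
    paste(AA_ALPHABET[ai], collapse = "")
  })
}

#' Generate a complete synthetic library with matched queries
#'
#' Builds one template per fold class (native sequence sampled from the
#' ground-truth potential on that structure) and `queries_per_class`
#' additional query sequences per class, each sampled independently on
#' its native structure. Optionally writes the on-disk layout consumed by
#' [run_predict()]/[run_train()]: `templates/<id>.pdb` +
#' `templates/<id>.region.tsv`, `queries/<id>.fasta` + `.topo` +
#' `.aln.fasta` (single-row MSA), and `answer_key.tsv`.
#'
#' @param spec a [fixture_spec()].
#' @param queries_per_class query sequences generated per fold class.
#' @param out_dir optional directory to write the library into.
#' @return A `tmf_library`: list with `templates` (named list of
#'   `tmf_structure`), `queries` (tibble `query_id`, `native_template`,
#'   `sequence`, `topology`), `spec`, and `dir` (NULL when not written).
#' @export
make_library <- function(spec = fixture_spec(), queries_per_class = 1L,
                         out_dir = NULL) {
  pot <- spec$ground_truth_potential
  templates <- list()
  qrows <- list()
  for (k in seq_len(spec$n_fold_classes)) {
    bare <- make_bundle(spec, k)
    native <- sample_sequence(bare, pot, temperature = spec$sampling_temperature,
                              seed = spec$rng_seed + 1000L * k)
    tpl <- make_bundle(spec, k, sequence = native)
    templates[[tpl$chain_id]] <- tpl
    for (q in seq_len(queries_per_class)) {
      qseq <- sample_sequence(bare, pot, temperature = spec$sampling_temperature,
                              seed = spec$rng_seed + 1000L * k + q)
      qrows[[length(qrows) + 1L]] <- tibble(
        query_id = sprintf("q_%s_%02d", tpl$chain_id, q),
        native_template = tpl$chain_id,
        sequence = qseq,
        topology = tpl$topology
      )
    }
  }
  queries <- bind_rows(qrows)
  lib <- structure(
    list(templates = templates, queries = queries, spec = spec, dir = NULL),
    class = "tmf_library"
  )
  if (!is.null(out_dir)) {
    write_library(lib, out_dir)
    lib$dir <- out_dir
  }
  lib
}

#' @export
print.tmf_library <- function(x, ...) {
  cat(sprintf("<tmf_library> %d template(s), %d query(ies)\n",
              length(x$templates), nrow(x$queries)))
  invisible(x)
}

#' Write / load the on-disk library layout
#'
#' @param lib a `tmf_library`.
#' @param dir directory.
#' @return `write_library`: `dir`, invisibly. `load_library`: a
#'   `tmf_library` (without the generating spec).
#' @export
write_library <- function(lib, dir) {
  tdir <- file.path(dir, "templates")
  qdir <- file.path(dir, "queries")
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(qdir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(lib$templates)) {
    write_template(lib$templates[[id]],
                   file.path(tdir, paste0(id, ".pdb")),
                   file.path(tdir, paste0(id, ".region.tsv")))
  }
  for (i in seq_len(nrow(lib$queries))) {
    q <- lib$queries[i, ]
    writeLines(c(paste0(">", q$query_id), q$sequence),
               file.path(qdir, paste0(q$query_id, ".fasta")))
    writeLines(q$topology, file.path(qdir, paste0(q$query_id, ".topo")))
    writeLines(c(paste0(">", q$query_id), q$sequence),
               file.path(qdir, paste0(q$query_id, ".aln.fasta")))
  }
  utils::write.table(
    lib$queries[, c("query_id", "native_template")],
    file.path(dir, "answer_key.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(dir)
}

#' @rdname write_library
#' @export
load_library <- function(dir) {
  tdir <- file.path(dir, "templates")
  qdir <- file.path(dir, "queries")
  pdbs <- sort(list.files(tdir, pattern = "\\.pdb$", full.names = TRUE))
  templates <- list()
  for (p in pdbs) {
    id <- sub("\\.pdb$", "", basename(p))
    templates[[id]] <- read_template(p, file.path(tdir, paste0(id, ".region.tsv")))
  }
  key <- utils::read.table(file.path(dir, "answer_key.tsv"),
                           sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  queries <- bind_rows(lapply(key$query_id, function(id) {
    tibble(
      query_id = id,
      native_template = key$native_template[key$query_id == id],
      sequence = read_query(file.path(qdir, paste0(id, ".fasta"))),
      topology = read_topology(file.path(qdir, paste0(id, ".topo")))
    )
  }))
  structure(list(templates = templates, queries = queries, spec = NULL, dir = dir),
            class = "tmf_library")
}
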