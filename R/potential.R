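# feature indexing for the 210 unordered amino-acid pairs + 20 lipid terms
PAIR_IDX <- local({
  m <- matrix(0L, N_AA, N_AA)
  m[upper.tri(m, diag = TRUE)] <- seq_len(N_AA * (N_AA + 1L) / 2L)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
})
N_PAIR <- N_AA * (N_AA + 1L) / 2L
N_FEAT <- N_PAIR + N_AA

#' Statistical potential container
#'
#' Holds the pair interaction energies (symmetric 20x20, dimensionless
#' energy units; lower = more favorable) and the 20 amino-acid-lipid
#' energies.
#'
#' @param epsilon symmetric 20x20 numeric matrix, rows/cols in
#'   [AA_ALPHABET] order.
#' @param h numeric 20-vector of lipid contact energies.
#' @return A `tmf_potential`.
#' @export
potential_set <- function(epsilon, h) {
  epsilon <- as.matrix(epsilon)
  stopifnot(identical(dim(epsilon), c(N_AA, N_AA)), length(h) == N_AA)
  if (max(abs(epsilon - t(epsilon))) > 1e-9) abort("epsilon must be symmetric")
  if (!all(is.finite(epsilon)) || !all(is.finite(h))) abort("non-finite potential entries")
  epsilon <- (epsilon + t(epsilon)) / 2
  dimnames(epsilon) <- list(AA_ALPHABET, AA_ALPHABET)
  structure(list(epsilon = epsilon, h = setNames(as.numeric(h), AA_ALPHABET)),
            class = "tmf_potential")
}

#' @rdname potential_set
#' @export
zero_potential <- function() {
  potential_set(matrix(0, N_AA, N_AA), rep(0, N_AA))
}

#' @export
print.tmf_potential <- function(x, ...) {
  cat(sprintf("<tmf_potential> 20x20 pair energies (range %.3f .. %.3f), 20 lipid energies\n",
              min(x$epsilon), max(x$epsilon)))
  invisible(x)
}

theta_vector <- function(potential) {
  c(potential$epsilon[upper.tri(potential$epsilon, diag = TRUE)], potential$h)
}

theta_to_potential <- function(theta) {
  eps <- matrix(0, N_AA, N_AA)
  eps[upper.tri(eps, diag = TRUE)] <- theta[seq_len(N_PAIR)]
  eps[lower.tri(eps)] <- t(eps)[lower.tri(eps)]
  potential_set(eps, theta[N_PAIR + seq_len(N_AA)])
}

#' Contact summary of a (structure, sequence) pairing
#'
#' Tabulates the pair-contact counts n (unordered amino-acid pairs, each
#' physical contact once) and the lipid-contact counts m for a sequence
#' threaded 1:1 onto a structure. Includes intra-chain contacts, symmetry
#' image contacts (partner identity taken from the same sequence) and one
#' lipid contact per lipid-exposed residue. Residues typed `X` (or any
#' nonstandard code) contribute no terms.
#'
#' @param structure a `tmf_structure`.
#' @param sequence amino-acid string of the same length as the chain;
#'   defaults to the structure's own (native) sequence.
#' @return A `tmf_contacts`: `n` (symmetric 20x20 count matrix where
#'   `sum(n[upper.tri])` equals the number of counted pairs), `m`
#'   (20-vector), `per_position_contacts` (tibble `a`,`b`),
#'   `per_position_lipid` (integer vector).
#' @export
contact_summary <- function(structure, sequence = NULL) {
  if (is.null(sequence)) sequence <- paste(structure$residues$aa, collapse = "")
  aa <- seq_chars(sequence)
  if (length(aa) != nrow(structure$residues)) {
    abort("sequence length does not match structure")
  }
  geom <- structure_contact_geometry(structure)
  ai <- aa_index(aa)
  f <- count_features(ai, geom$pair_a, geom$pair_b, geom$lipid)
  n <- matrix(0, N_AA, N_AA, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  n[upper.tri(n, diag = TRUE)] <- f[seq_len(N_PAIR)]
  n[lower.tri(n)] <- t(n)[lower.tri(n)]
  structure(
    list(
      n = n,
      m = setNames(f[N_PAIR + seq_len(N_AA)], AA_ALPHABET),
      per_position_contacts = tibble(a = geom$pair_a - 1L, b = geom$pair_b - 1L),
      per_position_lipid = geom$lipid - 1L
    ),
    class = "tmf_contacts"
  )
}

# positions (1-based) of all counted pairs and lipid contacts of a structure;
# cached on the object via attribute when called through threading
structure_contact_geometry <- function(structure) {
  pc <- pair_contacts(structure)
  ic <- interchain_contacts(structure)
  list(
    pair_a = c(pc$a, ic$index) + 1L,
    pair_b = c(pc$b, ic$partner_index) + 1L,
    lipid = lipid_exposed(structure) + 1L
  )
}

# 230-long feature vector of counts for one amino-acid assignment
count_features <- function(ai, pair_a, pair_b, lipid) {
  f <- numeric(N_FEAT)
  ia <- ai[pair_a]
  ib <- ai[pair_b]
  ok <- !is.na(ia) & !is.na(ib)
  if (any(ok)) {
    idx <- PAIR_IDX[cbind(ia[ok], ib[ok])]
    tab <- tabulate(idx, nbins = N_PAIR)
    f[seq_len(N_PAIR)] <- tab
  }
  il <- ai[lipid]
  il <- il[!is.na(il)]
  if (length(il) > 0L) {
    f[N_PAIR + seq_len(N_AA)] <- tabulate(il, nbins = N_AA)
  }
  f
}

#' Single-sequence threading energy
#'
#' The energy of a (conformation, sequence) pairing:
#' the sum over unordered amino-acid pairs of `epsilon_ij * n_ij` plus the
#' sum over amino-acid types of `h_i * m_i`.
#'
#' @param summary a `tmf_contacts` from [contact_summary()].
#' @param potential a `tmf_potential`.
#' @return Scalar energy.
#' @export
seq_energy <- function(summary, potential) {
  ut <- upper.tri(summary$n, diag = TRUE)
  sum(potential$epsilon[ut] * summary$n[ut]) + sum(potential$h * summary$m)
}

#' Profile (MSA) threading energy
#'
#' Average of the single-sequence energy over the M rows of a multiple
#' sequence alignment threaded through the same position mapping. Gap or
#' `X` characters in a row contribute no terms for that row.
#'
#' @param contacts list with 1-based position vectors `pair_a`, `pair_b`
#'   (contact pairs indexing MSA columns) and `lipid` (lipid-contact
#'   positions), e.g. built from a [contact_summary()]'s per-position
#'   lists.
#' @param msa a `tmf_msa` whose columns are the threaded positions.
#' @param potential a `tmf_potential`.
#' @return Scalar mean energy.
#' @export
msa_energy <- function(contacts, msa, potential) {
  if (msa$M < 1L) abort("no usable MSA rows")
  eps <- potential$epsilon
  h <- potential$h
  e <- vapply(seq_len(msa$M), function(k) {
    ai <- aa_index(msa$seqs[k, ])
    assignment_energy(ai, contacts$pair_a, contacts$pair_b, contacts$lipid, eps, h)
  }, numeric(1))
  mean(e)
}

assignment_energy <- function(ai, pair_a, pair_b, lipid, eps, h) {
  ia <- ai[pair_a]
  ib <- ai[pair_b]
  ok <- !is.na(ia) & !is.na(ib)
  epair <- if (any(ok)) sum(eps[cbind(ia[ok], ib[ok])]) else 0
  il <- ai[lipid]
  il <- il[!is.na(il)]
  epair + sum(h[il])
}

#' Training configuration
#'
#' Hyperparameters for [train_potential()]. Decoys are drawn once per run
#' (not per iteration) so the likelihood surface is fixed and the result
#' is deterministic given the seed.
#'
#' @param decoys_per_native shuffled decoy sequences per training chain.
#' @param learning_rate initial steepest-ascent step size.
#' @param max_iterations iteration cap.
#' @param convergence_tolerance max-norm gradient threshold.
#' @param rng_seed integer seed recorded in the output.
#' @return A `tmf_training_config` list.
#' @export
training_config <- function(decoys_per_native = 100L,
                            learning_rate = 0.1,
                            max_iterations = 500L,
                            convergence_tolerance = 1e-6,
                            rng_seed = 1L) {
  stopifnot(decoys_per_native >= 1L, learning_rate > 0,
            max_iterations >= 1L, convergence_tolerance > 0)
  structure(
    list(
      decoys_per_native = as.integer(decoys_per_native),
      learning_rate = learning_rate,
      max_iterations = as.integer(max_iterations),
      convergence_tolerance = convergence_tolerance,
      rng_seed = as.integer(rng_seed)
    ),
    class = "tmf_training_config"
  )
}

#' Shuffled-sequence decoys
#'
#' Non-native alternatives for maximum-likelihood training: uniform random
#' permutations of the native residues threaded onto the same structure
#' positions. Deterministic given the seed in `config`.
#'
#' @param structure a `tmf_structure` (fixes the number of positions).
#' @param native_sequence the native amino-acid string.
#' @param config a [training_config()].
#' @return Character vector of `decoys_per_native` shuffled sequences.
#' @export
make_decoys <- function(structure, native_sequence, config = training_config()) {
  aa <- seq_chars(native_sequence)
  if (length(aa) < 2L) abort("sequence must have at least 2 residues")
  if (length(aa) != nrow(structure$residues)) {
    abort("sequence length does not match structure")
  }
  withr_seed(config$rng_seed, {
    vapply(seq_len(config$decoys_per_native), function(i) {
      paste(sample(aa), collapse = "")
    }, character(1))
  })
}

# evaluate an expression under a local RNG seed without disturbing the
# caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Train the statistical potential by maximum likelihood against decoys
#'
#' For every training chain the native sequence competes against
#' shuffled-sequence decoys in a Boltzmann softmax: the likelihood of a
#' chain is `exp(-E_native) / sum_k exp(-E_k)` with k running over the
#' native and its decoys. The total log likelihood is maximized by
#' steepest ascent on the pair and lipid energies, with backtracking
#' halving of the step so the objective never decreases across accepted
#' steps. The gradient is the expected contact-count vector under the
#' softmax minus the native counts.
#'
#' @param training_set list of items, each a list with `structure` (a
#'   `tmf_structure`) and optionally `sequence` (defaults to the native
#'   sequence of the structure).
#' @param config a [training_config()].
#' @param init optional starting `tmf_potential` (default: all zeros).
#' @return A `tmf_potential` with attributes `objective` (trace over
#'   accepted iterations), `converged`, `iterations`, `config`.
#' @export
train_potential <- function(training_set, config = training_config(),
                            init = NULL) {
  if (length(training_set) < 1L) abort("need at least one training chain")
  feats <- vector("list", length(training_set))
  for (t in seq_along(training_set)) {
    item <- training_set[[t]]
    s <- item$structure
    seqn <- item$sequence %||% paste(s$residues$aa, collapse = "")
    geom <- structure_contact_geometry(s)
    cfg_t <- config
    cfg_t$rng_seed <- config$rng_seed + t
    decoys <- make_decoys(s, seqn, cfg_t)
    cand <- c(seqn, decoys)
    fm <- vapply(cand, function(sq) {
      count_features(aa_index(seq_chars(sq)), geom$pair_a, geom$pair_b, geom$lipid)
    }, numeric(N_FEAT))
    feats[[t]] <- t(fm) # (1 + D) x N_FEAT, native row first
  }

  obj_grad <- function(theta) {
    ll <- 0
    grad <- numeric(N_FEAT)
    for (fm in feats) {
      en <- as.numeric(fm %*% theta)
      w <- -en
      w <- w - max(w)
      p <- exp(w) / sum(exp(w))
      ll <- ll + log(p[1])
      grad <- grad + as.numeric(crossprod(fm, p)) - fm[1, ]
    }
    list(ll = ll, grad = grad)
  }

  theta <- if (is.null(init)) numeric(N_FEAT) else theta_vector(init)
  og <- obj_grad(theta)
  if (!is.finite(og$ll)) abort("objective not finite at initialization")
  trace <- og$ll
  step0 <- config$learning_rate
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    g <- og$grad
    if (max(abs(g)) < config$convergence_tolerance) {
      converged <- TRUE
      iter <- iter - 1L
      break
    }
    step <- step0
    repeat {
      cand <- theta + step * g
      og2 <- obj_grad(cand)
      if (is.nan(og2$ll)) {
        abort(sprintf("objective became NaN at iteration %d", iter))
      }
      if (og2$ll >= og$ll) break
      step <- step / 2
      if (step < 1e-12) break
    }
    if (og2$ll < og$ll) { # no ascent direction progress possible
      converged <- TRUE
      break
    }
    theta <- cand
    og <- og2
    trace <- c(trace, og$ll)
  }
  pot <- theta_to_potential(theta)
  attr(pot, "objective") <- trace
  attr(pot, "converged") <- converged
  attr(pot, "iterations") <- iter
  attr(pot, "config") <- config
  pot
}

#' Tidy the pair energies of a potential
#' @param x a `tmf_potential`.
#' @param ... unused.
#' @return Tibble with `aa_i`, `aa_j` (i <= j in alphabet order),
#'   `epsilon`; lipid terms via [glance.tmf_potential()] or `x$h`.
#' @exportS3Method generics::tidy
tidy.tmf_potential <- function(x, ...) {
  ut <- which(upper.tri(x$epsilon, diag = TRUE), arr.ind = TRUE)
  tibble(
    aa_i = AA_ALPHABET[ut[, 1]],
    aa_j = AA_ALPHABET[ut[, 2]],
    epsilon = x$epsilon[ut]
  )
}

#' One-row summary of a trained potential
#' @param x a `tmf_potential`.
#' @param ... unused.
#' @return Tibble with final objective, iterations, convergence flag.
#' @exportS3Method generics::glance
glance.tmf_potential <- function(x, ...) {
  obj <- attr(x, "objective")
  tibble(
    objective = if (is.null(obj)) NA_real_ else obj[length(obj)],
    iterations = attr(x, "iterations") %||% NA_integer_,
    converged = attr(x, "converged") %||% NA
  )
}

#' Write / read a potential as TSV
#'
#' Layout: a `20x20` pair-energy block (header row and row names are
#' one-letter codes) followed by a blank line and a 20-row two-column
#' lipid block.
#'
#' @param potential a `tmf_potential`.
#' @param path file path.
#' @return `write_potential`: the path, invisibly.
#' @export
write_potential <- function(potential, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("aa", AA_ALPHABET), collapse = "\t"), con)
  for (i in seq_len(N_AA)) {
    writeLines(paste(c(AA_ALPHABET[i],
                       format(potential$epsilon[i, ], digits = 12)),
                     collapse = "\t"), con)
  }
  writeLines("", con)
  for (i in seq_len(N_AA)) {
    writeLines(paste(c(AA_ALPHABET[i], format(potential$h[i], digits = 12)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_potential
#' @export
read_potential <- function(path) {
  lines <- readLines(path)
  blank <- which(!nzchar(trimws(lines)))[1]
  head_block <- lines[2:(blank - 1L)]
  eps <- do.call(rbind, lapply(head_block, function(l) {
    as.numeric(strsplit(l, "\t")[[1]][-1])
  }))
  tail_block <- lines[(blank + 1L):length(lines)]
  tail_block <- tail_block[nzchar(trimws(tail_block))]
  h <- vapply(tail_block, function(l) as.numeric(strsplit(l, "\t")[[1]][2]),
              numeric(1))
  potential_set(eps, unname(h))
}

#' Write a potential as JSON with provenance metadata
#'
#' @inheritParams write_potential
#' @param metadata named list stored alongside the energies (e.g. training
#'   seed, config, dataset hash).
#' @return The path, invisibly.
#' @export
write_potential_json <- function(potential, path, metadata = list()) {
  jsonlite::write_json(
    list(
      alphabet = AA_ALPHABET,
      epsilon = unname(as.data.frame(potential$epsilon)),
      h = unname(potential$h),
      metadata = metadata
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_potential_json
#' @export
read_potential_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  potential_set(as.matrix(obj$epsilon), obj$h)
}
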