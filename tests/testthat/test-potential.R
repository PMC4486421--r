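test_that("single-sequence energy equals the naive double-loop oracle", {
  pot <- random_potential(1)
  # no standard residues -> every count zero -> energy 0
  s0 <- line_structure(c("X", "X"), x = c(0, 3), z = c(0, 0))
  expect_equal(seq_energy(contact_summary(s0), pot), 0)

  # one Leu-Leu contact, eps_LL = -1, no lipid terms
  sL <- line_structure(rep("L", 7), x = c(0, 30, 60, 90, 120, 3, 150))
  eps <- matrix(0, 20, 20)
  iL <- which(AA_ALPHABET == "L")
  eps[iL, iL] <- -1
  potL <- potential_set(eps, rep(0, 20))
  expect_equal(seq_energy(contact_summary(sL), potL), -1)

  # random count matrices against the elementwise oracle
  set.seed(8)
  for (r in 1:5) {
    n <- matrix(rpois(400, 1), 20, 20)
    n[lower.tri(n)] <- t(n)[lower.tri(n)]
    m <- rpois(20, 2)
    summ <- structure(list(n = n, m = m), class = "tmf_contacts")
    p <- random_potential(100 + r)
    expect_equal(seq_energy(summ, p), oracle_seq_energy(n, m, p$epsilon, p$h))
  }
})

test_that("energy is linear in the potential", {
  s <- mini_bundle(1)
  seqn <- sample_sequence(s, random_potential(2), temperature = 1, seed = 4)
  summ <- contact_summary(s, seqn)
  pot <- random_potential(3)
  e1 <- seq_energy(summ, pot)
  for (alpha in c(-1, 0.5, 3)) {
    scaled <- potential_set(alpha * pot$epsilon, alpha * pot$h)
    expect_equal(seq_energy(summ, scaled), alpha * e1)
  }
})

test_that("contact summary counts are symmetric and complete", {
  s <- mini_bundle(2)
  summ <- contact_summary(s)
  expect_equal(summ$n, t(summ$n))
  expect_true(all(summ$n >= 0) && all(summ$m >= 0))
  # unordered pair count: upper triangle (incl. diagonal) sums to the
  # number of counted contacts
  ut <- upper.tri(summ$n, diag = TRUE)
  expect_equal(sum(summ$n[ut]), nrow(summ$per_position_contacts))
  expect_equal(sum(summ$m), length(summ$per_position_lipid))
})

test_that("profile energy reduces to and averages single-sequence energies", {
  s <- mini_bundle(1)
  pot <- random_potential(4)
  seq1 <- sample_sequence(s, pot, temperature = 1, seed = 1)
  seq2 <- sample_sequence(s, pot, temperature = 1, seed = 2)
  geom <- list(
    pair_a = contact_summary(s)$per_position_contacts$a + 1L,
    pair_b = contact_summary(s)$per_position_contacts$b + 1L,
    lipid = contact_summary(s)$per_position_lipid + 1L
  )
  e1 <- seq_energy(contact_summary(s, seq1), pot)
  e2 <- seq_energy(contact_summary(s, seq2), pot)
  expect_equal(msa_energy(geom, msa_profile(seq1), pot), e1)
  expect_equal(msa_energy(geom, msa_profile(rep(seq1, 5)), pot), e1)
  expect_equal(msa_energy(geom, msa_profile(c(seq1, seq2)), pot),
               mean(c(e1, e2)))
  # a row of gaps contributes no terms, dragging the mean toward zero
  gap_row <- paste(rep("-", nchar(seq1)), collapse = "")
  expect_equal(msa_energy(geom, msa_profile(c(seq1, gap_row)), pot), e1 / 2)
})

test_that("decoys are seeded permutations of the native residues", {
  s <- mini_bundle(1)
  native <- sample_sequence(s, random_potential(5), temperature = 1, seed = 9)
  cfg <- training_config(decoys_per_native = 20, rng_seed = 123)
  d1 <- make_decoys(s, native, cfg)
  d2 <- make_decoys(s, native, cfg)
  expect_identical(d1, d2)
  expect_length(d1, 20)
  for (d in d1[1:5]) {
    expect_equal(sort(strsplit(d, "")[[1]]), sort(strsplit(native, "")[[1]]))
  }
  d3 <- make_decoys(s, native, training_config(decoys_per_native = 20,
                                               rng_seed = 124))
  expect_false(identical(d1, d3))
  # homopolymer: every permutation is the native sequence
  homo <- paste(rep("L", nrow(s$residues)), collapse = "")
  expect_true(all(make_decoys(s, homo, cfg) == homo))
  expect_error(make_decoys(s, "A", cfg), "at least 2")
})

test_that("training on a homopolymer leaves the zero potential untouched", {
  s <- mini_bundle(1)
  homo <- paste(rep("L", nrow(s$residues)), collapse = "")
  fit <- train_potential(
    list(list(structure = s, sequence = homo)),
    training_config(decoys_per_native = 10, rng_seed = 3, max_iterations = 50)
  )
  expect_true(attr(fit, "converged"))
  expect_equal(attr(fit, "iterations"), 0L)
  expect_equal(unname(fit$epsilon), matrix(0, 20, 20))
  expect_equal(unname(fit$h), rep(0, 20))
})

test_that("training recovers the sign structure of a two-letter toy", {
  # contacts pair positions {0,6} and {1,7}; native puts A at the contact
  # positions and V elsewhere, so A-A contacts are favored in natives
  xs <- c(0, 30, 60, 90, 120, 150, 3, 33)
  natives <- list("AVVVVVAV", "AAVVVVAA")
  items <- lapply(natives, function(sq) {
    list(structure = line_structure(strsplit(sq, "")[[1]], x = xs),
         sequence = sq)
  })
  fit <- train_potential(items, training_config(decoys_per_native = 200,
                                                rng_seed = 17,
                                                max_iterations = 150))
  iA <- which(AA_ALPHABET == "A")
  iV <- which(AA_ALPHABET == "V")
  expect_lt(fit$epsilon[iA, iA], fit$epsilon[iA, iV])

  # independent oracle: exhaustive grid search of the same softmax
  # likelihood restricted to the (eAA, eAV, eVV) subspace
  count_pairs <- function(sq) {
    ch <- strsplit(sq, "")[[1]]
    pairs <- rbind(c(1, 7), c(2, 8))
    cnt <- c(AA = 0, AV = 0, VV = 0)
    for (r in 1:2) {
      ab <- sort(ch[pairs[r, ]])
      key <- paste(ab, collapse = "")
      key <- c(AA = "AA", AV = "AV", VV = "VV")[[key]]
      cnt[key] <- cnt[key] + 1
    }
    cnt
  }
  decoy_sets <- lapply(natives, function(sq) {
    set.seed(99)
    vapply(1:200, function(i) paste(sample(strsplit(sq, "")[[1]]), collapse = ""),
           character(1))
  })
  loglik <- function(th) {
    tot <- 0
    for (i in seq_along(natives)) {
      cand <- c(natives[[i]], decoy_sets[[i]])
      en <- vapply(cand, function(sq) sum(count_pairs(sq) * th), numeric(1))
      w <- -en - max(-en)
      tot <- tot + w[1] - log(sum(exp(w)))
    }
    tot
  }
  grid <- seq(-2, 2, by = 0.25)
  best <- c(0, 0, 0)
  best_ll <- -Inf
  for (a in grid) for (b in grid) for (v in grid) {
    ll <- loglik(c(AA = a, AV = b, VV = v))
    if (ll > best_ll) {
      best_ll <- ll
      best <- c(a, b, v)
    }
  }
  expect_lt(best[1], best[2]) # grid-search oracle agrees: eAA < eAV
})

test_that("the training objective is monotone non-decreasing", {
  s <- mini_bundle(1)
  pot <- random_potential(6)
  items <- lapply(1:3, function(k) {
    list(structure = s,
         sequence = sample_sequence(s, pot, temperature = 0.7, seed = 30 + k))
  })
  fit <- train_potential(items, training_config(decoys_per_native = 50,
                                                rng_seed = 2,
                                                max_iterations = 80))
  trace <- attr(fit, "objective")
  expect_gt(length(trace), 1)
  expect_true(all(diff(trace) >= 0))
  expect_true(all(is.finite(theta_diff <- c(fit$epsilon, fit$h))))
})

test_that("a constant shift of all pair energies preserves decoy ranking", {
  s <- mini_bundle(2)
  pot <- random_potential(7)
  native <- sample_sequence(s, pot, temperature = 0.7, seed = 5)
  cands <- c(native, make_decoys(s, native, training_config(
    decoys_per_native = 15, rng_seed = 44
  )))
  shifted <- potential_set(pot$epsilon + 0.7, pot$h)
  e0 <- vapply(cands, function(sq) seq_energy(contact_summary(s, sq), pot),
               numeric(1))
  e1 <- vapply(cands, function(sq) seq_energy(contact_summary(s, sq), shifted),
               numeric(1))
  # all candidates share the structural contact count, so energies shift
  # by the same constant and the ranking is unchanged
  expect_equal(diff(range(e1 - e0)), 0, tolerance = 1e-9)
  expect_identical(order(e0), order(e1))
})

test_that("potential files round-trip through TSV and JSON", {
  pot <- random_potential(9)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_potential(pot, tmp)
  pot2 <- read_potential(tmp)
  expect_equal(pot2$epsilon, pot$epsilon, tolerance = 1e-9)
  expect_equal(pot2$h, pot$h, tolerance = 1e-9)
  tmp2 <- withr::local_tempfile(fileext = ".json")
  write_potential_json(pot, tmp2, metadata = list(seed = 9))
  pot3 <- read_potential_json(tmp2)
  expect_equal(pot3$epsilon, pot$epsilon)
  expect_equal(pot3$h, pot$h)
})
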