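test_that("pair contacts match a brute-force scan and use strict boundaries", {
  # boundary cases on a hand-built line: distances 4 and exactly 5,
  # separations 4 (excluded) and 5 (allowed)
  s <- line_structure(rep("A", 8), x = c(0, 20, 40, 60, 4, 100, 120, 65))
  # index pairs: (0,4) distance 4, separation 4 -> excluded;
  # (3,7) distance 5 exactly, separation 4 -> excluded anyway; craft more:
  pc <- pair_contacts(s)
  expect_equal(nrow(pc), 0L)

  s2 <- line_structure(rep("L", 7), x = c(0, 30, 60, 90, 120, 3, 150))
  # (0,5): distance 3, separation 5 -> included
  pc2 <- pair_contacts(s2)
  expect_equal(unname(as.matrix(pc2)), matrix(c(0L, 5L), 1))

  # exactly 5.0 A at separation 6 -> excluded (strict <)
  s3 <- line_structure(rep("A", 7), x = c(0, 30, 60, 90, 120, 150, 5))
  expect_equal(nrow(pair_contacts(s3)), 0L)

  # randomized geometry vs O(n^2) oracle
  set.seed(21)
  for (rep in 1:3) {
    n <- 30
    s4 <- line_structure(sample(AA_ALPHABET, n, TRUE),
                         x = runif(n, 0, 18), z = runif(n, -6, 6))
    got <- as.matrix(pair_contacts(s4))
    want <- oracle_pair_contacts(s4)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(unname(got), unname(want[order(want[, 1], want[, 2]), ,
                                             drop = FALSE]))
    }
  }
})

test_that("pair contacts on bundles equal the brute-force oracle", {
  s <- mini_bundle(1)
  got <- as.matrix(pair_contacts(s))
  want <- oracle_pair_contacts(s)
  expect_gt(nrow(got), 0)
  expect_equal(unname(got), unname(want[order(want[, 1], want[, 2]), ]))
})

test_that("symmetry-image contacts equal an explicit two-copy scan", {
  expect_equal(nrow(interchain_contacts(mini_bundle(1))), 0L)

  # C2 rotation about z through x = 15: maps x -> 30 - x, y -> -y
  c2 <- matrix(c(-1, 0, 0, 30,
                 0, -1, 0, 0,
                 0, 0, 1, 0), 3, 4, byrow = TRUE)
  s <- line_structure(c("A", "C", "D", "E", "F", "K"),
                      x = c(0, 3, 6, 9, 12, 14),
                      symmetry_ops = list(c2))
  got <- interchain_contacts(s)
  want <- oracle_interchain(s)
  expect_gt(nrow(got), 0)
  expect_equal(unname(as.matrix(got[, c("index", "partner_index", "op")])),
               unname(want[order(want[, 3], want[, 1], want[, 2]), ]))
  # no sequence-separation filter across chains: adjacent indices allowed
  expect_true(any(abs(got$index - got$partner_index) <= 4))
  # self-consistency under symmetry: the contact pair multiset is closed
  # under swapping which copy is "self"
  key_fwd <- paste(got$index, got$partner_index)
  key_rev <- paste(got$partner_index, got$index)
  expect_setequal(key_fwd, key_rev)
})

test_that("lipid exposure: isolated helices are exposed, slab rule applies", {
  s <- mini_bundle(1)
  exposed <- lipid_exposed(s)
  in_slab <- abs(s$residues$z) <= s$half_thickness
  # nothing occludes an isolated pair of loosely packed helices
  expect_setequal(exposed, s$residues$index[in_slab])
  # residues outside the slab are never exposed
  expect_false(any(!in_slab[exposed + 1L]))
})

test_that("lipid exposure is unchanged by atoms outside the slab", {
  s <- mini_bundle(2)
  base <- lipid_exposed(s)
  s2 <- s
  extra <- tibble::tibble(res_index = 0L, name = "CB",
                          x = c(50, -50), y = 0, z = c(30, -30))
  s2$atoms <- dplyr::bind_rows(s2$atoms, extra)
  expect_equal(lipid_exposed(s2), base)
})

test_that("buried residues agree with a Monte-Carlo surface oracle", {
  # tight hub-and-spokes bundle: the central helix is occluded
  spec <- fixture_spec(helices_per_bundle = 4L, inter_helix_distance = 7.0)
  s <- make_bundle(spec, 4)
  exposed <- lipid_exposed(s)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  radii <- rep(1.70, nrow(xyz))
  mc <- oracle_exposed_atoms(xyz, radii, n_dirs = 600)
  slab <- abs(s$atoms$z) <= s$half_thickness
  # per-residue Monte-Carlo free-surface fraction (atoms inside the slab)
  frac <- vapply(s$residues$index, function(r) {
    sel <- s$atoms$res_index == r & slab
    if (!any(sel)) 0 else max(mc[sel]) / 600
  }, numeric(1))
  expect_gt(length(setdiff(s$residues$index, exposed)), 0) # some burial
  # decisively exposed by the oracle -> exposed by the package
  expect_true(all(s$residues$index[frac > 0.02] %in% exposed))
  # decisively buried by the oracle -> buried by the package
  expect_false(any(s$residues$index[frac == 0] %in% exposed))
})

test_that("z-distribution layers match an independent histogram", {
  s1 <- line_structure("A", x = 0, z = -14.5, half = 15)
  zd1 <- build_z_distribution(list(s1))
  expect_equal(unname(zd1$freq[15, ]), c(1, rep(0, 19)) * 1)
  expect_equal(unname(which(zd1$freq[15, ] == 1)), which(AA_ALPHABET == "A"))

  templates <- lapply(1:3, function(k) {
    spec <- mini_spec()
    seqn <- sample_sequence(make_bundle(spec, (k %% 2) + 1L),
                            spec$ground_truth_potential,
                            temperature = 0.8, seed = k)
    make_bundle(spec, (k %% 2) + 1L, sequence = seqn)
  })
  zd <- build_z_distribution(templates)
  counts <- oracle_z_histogram(templates)
  expect_equal(unname(zd$counts), unname(counts))
  populated <- rowSums(counts) > 0
  expect_equal(rowSums(zd$freq[populated, , drop = FALSE]),
               rep(1, sum(populated)), ignore_attr = TRUE)
  # empty layers fall back to the global distribution and still sum to 1
  expect_equal(unname(rowSums(zd$freq)), rep(1, 15))
  global <- colSums(counts) / sum(counts)
  if (any(!populated)) {
    expect_equal(unname(zd$freq[which(!populated)[1], ]), unname(global))
  }
  expect_error(build_z_distribution(list()), "empty")
})

test_that("z-distribution TSV round-trips", {
  zd <- build_z_distribution(list(mini_bundle(1)))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_z_distribution(zd, tmp)
  zd2 <- read_z_distribution(tmp)
  expect_equal(zd2$freq, zd$freq, tolerance = 1e-12, ignore_attr = TRUE)
})
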