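#' Intra-chain residue contacts
#'
#' Two residues are in contact when the distance between their interaction
#' centers (C-beta, C-alpha for glycine) is strictly less than `cutoff`
#' and their sequence separation is strictly greater than
#' `min_separation`. A pair at exactly 5.0 Angstrom is therefore not a
#' contact, and neither is a pair separated by exactly 4 positions.
#'
#' @param structure a `tmf_structure`.
#' @param cutoff contact distance in Angstrom (default 5).
#' @param min_separation minimum |i - j| minus one, i.e. pairs with
#'   separation > 4 count (default 4).
#' @return Tibble of unordered pairs `a`, `b` (0-based residue indices,
#'   `a < b`), each pair once.
#' @export
pair_contacts <- function(structure, cutoff = 5, min_separation = 4) {
  res <- structure$residues
  n <- nrow(res)
  if (n < 2L) return(tibble(a = integer(), b = integer()))
  xyz <- as.matrix(res[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  idx <- res$index
  sep <- abs(outer(idx, idx, "-"))
  hit <- which(d < cutoff & sep > min_separation & upper.tri(d), arr.ind = TRUE)
  tibble(a = idx[hit[, 1]], b = idx[hit[, 2]]) |>
    arrange(.data$a, .data$b)
}

apply_op <- function(xyz, op) {
  t(op[, 1:3] %*% t(xyz) + op[, 4])
}

#' Cross-chain contacts under homo-oligomer symmetry
#'
#' For homo-oligomeric templates a periodic boundary condition is applied:
#' every non-identity symmetry operator generates an image copy of the
#' chain, and contacts between the representative chain and each image are
#' collected under the same distance rule as [pair_contacts()] but with no
#' sequence-separation filter (the image is a different molecule).
#'
#' @inheritParams pair_contacts
#' @return Tibble with `index` (residue of the representative chain),
#'   `partner_index` (underlying residue index of the image copy, whose
#'   threaded amino acid is the partner identity), `partner_aa` (the
#'   template's own amino acid at that position) and `op` (operator number,
#'   2-based as stored).
#' @export
interchain_contacts <- function(structure, cutoff = 5) {
  res <- structure$residues
  xyz <- as.matrix(res[, c("x", "y", "z")])
  out <- list()
  ops <- structure$symmetry_ops
  if (length(ops) >= 2L) {
    for (k in seq_along(ops)[-1]) {
      img <- apply_op(xyz, ops[[k]])
      d2 <- outer(rowSums(xyz^2), rowSums(img^2), "+") - 2 * xyz %*% t(img)
      hit <- which(d2 < cutoff^2, arr.ind = TRUE)
      if (nrow(hit) > 0L) {
        out[[length(out) + 1L]] <- tibble(
          index = res$index[hit[, 1]],
          partner_index = res$index[hit[, 2]],
          partner_aa = res$aa[hit[, 2]],
          op = k
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(index = integer(), partner_index = integer(),
                  partner_aa = character(), op = integer()))
  }
  bind_rows(out) |> arrange(.data$op, .data$index, .data$partner_index)
}

# van der Waals radii by element guess from atom name
atom_radius <- function(name) {
  first <- substr(gsub("^[0-9]+", "", name), 1, 1)
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)[first]
  ifelse(is.na(r), 1.80, r)
}

# deterministic Fibonacci lattice on the unit sphere
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

# fraction of each atom's probe-extended sphere not buried by other atoms
sasa_exposed_points <- function(xyz, radii, probe = 1.4, n_points = 92L,
                                dirs = NULL) {
  n <- nrow(xyz)
  if (is.null(dirs)) dirs <- sphere_points(n_points)
  rr <- radii + probe
  exposed <- integer(n)
  for (i in seq_len(n)) {
    pts <- sweep(dirs * rr[i], 2, xyz[i, ], "+")
    others <- setdiff(which(
      rowSums(sweep(xyz, 2, xyz[i, ])^2) < (rr[i] + max(rr))^2
    ), i)
    free <- rep(TRUE, nrow(pts))
    for (j in others) {
      if (!any(free)) break
      d2 <- rowSums(sweep(pts[free, , drop = FALSE], 2, xyz[j, ])^2)
      keep <- d2 >= rr[j]^2
      free[free] <- keep
    }
    exposed[i] <- sum(free)
  }
  exposed
}

#' Lipid-exposed residues
#'
#' A residue is in contact with the lipid phase when at least one of its
#' heavy atoms lies inside the membrane slab (|z| <= half thickness;
#' the exact boundary counts as inside) and is accessible to a probe
#' sphere of radius 1.4 Angstrom on the surface of the full oligomeric
#' coordinate set (all symmetry images, plus any unknown-identity
#' neighbor centers as occluders). Atoms outside the slab never make a
#' residue lipid-exposed but still occlude.
#'
#' @param structure a `tmf_structure`.
#' @param probe probe radius in Angstrom (default 1.4).
#' @param n_points surface sample points per atom (default 92).
#' @return Sorted integer vector of 0-based residue indices.
#' @export
lipid_exposed <- function(structure, probe = 1.4, n_points = 92L) {
  at <- structure$atoms
  if (nrow(at) == 0L) {
    warn("no heavy atoms; falling back to interaction-center-only exposure test")
    at <- tibble(res_index = structure$residues$index, name = "CB",
                 x = structure$residues$x, y = structure$residues$y,
                 z = structure$residues$z)
  }
  xyz0 <- as.matrix(at[, c("x", "y", "z")])
  rad0 <- atom_radius(at$name)
  xyz <- xyz0
  rad <- rad0
  ops <- structure$symmetry_ops
  if (length(ops) >= 2L) {
    for (k in seq_along(ops)[-1]) {
      xyz <- rbind(xyz, apply_op(xyz0, ops[[k]]))
      rad <- c(rad, rad0)
    }
  }
  if (!is.null(structure$neighbor_centers)) {
    xyz <- rbind(xyz, as.matrix(structure$neighbor_centers[, c("x", "y", "z")]))
    rad <- c(rad, rep(1.80, nrow(structure$neighbor_centers)))
  }
  exposed_pts <- sasa_exposed_points(xyz, rad, probe = probe, n_points = n_points)
  n_self <- nrow(at)
  in_slab <- abs(at$z) <= structure$half_thickness
  ok <- exposed_pts[seq_len(n_self)] > 0L & in_slab
  sort(unique(at$res_index[ok]))
}

#' z-layer amino-acid distribution
#'
#' Slices the membrane-frame space into 1 Angstrom layers of |z| from 0 to
#' 15 and tabulates the amino-acid composition of interaction centers per
#' layer over a set of template chains. The normalized distributions stand
#' in for the unknown residues of surrounding chains in hetero-oligomers.
#' Residues with |z| >= 15 are ignored; layers with no observations fall
#' back to the global (all-layer) distribution.
#'
#' @param templates list of `tmf_structure`.
#' @param n_layers number of 1-Angstrom layers (default 15).
#' @return A `tmf_zdist`: `freq` (n_layers x 20 matrix, rows sum to 1),
#'   `counts` (raw counts), `n_layers`.
#' @export
build_z_distribution <- function(templates, n_layers = 15L) {
  if (length(templates) == 0L) abort("empty template list")
  counts <- matrix(0, nrow = n_layers, ncol = N_AA,
                   dimnames = list(NULL, AA_ALPHABET))
  for (s in templates) {
    res <- s$residues
    ok <- res$aa %in% AA_ALPHABET & abs(res$z) < n_layers
    layer <- floor(abs(res$z[ok])) + 1L
    ai <- aa_index(res$aa[ok])
    for (r in seq_along(layer)) {
      counts[layer[r], ai[r]] <- counts[layer[r], ai[r]] + 1
    }
  }
  global <- colSums(counts)
  if (sum(global) == 0) abort("no residues inside the layered region")
  global <- global / sum(global)
  freq <- counts
  for (l in seq_len(n_layers)) {
    tot <- sum(counts[l, ])
    freq[l, ] <- if (tot > 0) counts[l, ] / tot else global
  }
  structure(list(freq = freq, counts = counts, n_layers = n_layers),
            class = "tmf_zdist")
}

#' @export
print.tmf_zdist <- function(x, ...) {
  cat(sprintf("<tmf_zdist> %d layers x %d amino acids (%d residues)\n",
              x$n_layers, ncol(x$freq), sum(x$counts)))
  invisible(x)
}

#' Tidy a z-layer distribution into long format
#' @param x a `tmf_zdist`.
#' @param ... unused.
#' @return Tibble with `layer` (0-based lower |z| bound), `aa`, `freq`.
#' @exportS3Method generics::tidy
tidy.tmf_zdist <- function(x, ...) {
  tibble(
    layer = rep(seq_len(x$n_layers) - 1L, times = ncol(x$freq)),
    aa = rep(colnames(x$freq), each = x$n_layers),
    freq = as.numeric(x$freq)
  )
}

#' Write / read a z-layer distribution as TSV
#'
#' 15 rows (layers) by 20 frequency columns, tab separated, with a header
#' row of one-letter codes.
#'
#' @param zdist a `tmf_zdist`.
#' @param path file path.
#' @return `write_z_distribution`: the path, invisibly.
#' @export
write_z_distribution <- function(zdist, path) {
  utils::write.table(
    as.data.frame(zdist$freq), path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_z_distribution
#' @export
read_z_distribution <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  if (!identical(colnames(m), AA_ALPHABET)) abort("unexpected z-distribution columns")
  structure(list(freq = m, counts = m * NA, n_layers = nrow(m)),
            class = "tmf_zdist")
}

zdist_layer <- function(zdist, z) {
  l <- floor(abs(z)) + 1
  l[l > zdist$n_layers] <- NA_integer_
  l
}
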