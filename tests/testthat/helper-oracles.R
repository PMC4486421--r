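# Independent oracle implementations: naive loops, quadrature and Monte
# Carlo, deliberately sharing no code with the package internals.

oracle_pair_contacts <- function(structure, cutoff = 5, min_sep = 4) {
  res <- structure$residues
  out <- NULL
  n <- nrow(res)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- sqrt((res$x[i] - res$x[j])^2 + (res$y[i] - res$y[j])^2 +
                  (res$z[i] - res$z[j])^2)
      if (d < cutoff && abs(res$index[i] - res$index[j]) > min_sep) {
        out <- rbind(out, c(res$index[i], res$index[j]))
      }
    }
  }
  out
}

# explicit two-copy (or k-copy) scan: materialize every image chain and
# collect cross pairs
oracle_interchain <- function(structure, cutoff = 5) {
  res <- structure$residues
  xyz <- as.matrix(res[, c("x", "y", "z")])
  out <- NULL
  for (k in seq_along(structure$symmetry_ops)[-1]) {
    op <- structure$symmetry_ops[[k]]
    img <- t(op[, 1:3] %*% t(xyz) + op[, 4])
    for (i in seq_len(nrow(xyz))) {
      for (j in seq_len(nrow(xyz))) {
        if (sqrt(sum((xyz[i, ] - img[j, ])^2)) < cutoff) {
          out <- rbind(out, c(res$index[i], res$index[j], k))
        }
      }
    }
  }
  out
}

# Monte Carlo surface test: random probe directions, fresh RNG stream
oracle_exposed_atoms <- function(xyz, radii, probe = 1.4, n_dirs = 400L,
                                 seed = 99L) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n_dirs), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  vapply(seq_len(nrow(xyz)), function(i) {
    pts <- sweep(u * (radii[i] + probe), 2, xyz[i, ], "+")
    free <- 0L
    for (p in seq_len(n_dirs)) {
      blocked <- FALSE
      for (j in seq_len(nrow(xyz))) {
        if (j == i) next
        if (sum((pts[p, ] - xyz[j, ])^2) < (radii[j] + probe)^2) {
          blocked <- TRUE
          break
        }
      }
      if (!blocked) free <- free + 1L
    }
    free
  }, integer(1))
}

oracle_z_histogram <- function(templates, n_layers = 15) {
  counts <- matrix(0, n_layers, 20, dimnames = list(NULL, AA_ALPHABET))
  for (s in templates) {
    for (r in seq_len(nrow(s$residues))) {
      az <- abs(s$residues$z[r])
      aa <- s$residues$aa[r]
      if (az < n_layers && aa %in% AA_ALPHABET) {
        counts[floor(az) + 1, aa] <- counts[floor(az) + 1, aa] + 1
      }
    }
  }
  counts
}

oracle_seq_energy <- function(n, m, eps, h) {
  tot <- 0
  for (i in 1:20) {
    for (j in i:20) tot <- tot + eps[i, j] * n[i, j]
    tot <- tot + h[i] * m[i]
  }
  unname(tot)
}

# error function by adaptive quadrature of its defining integral
oracle_erf <- function(x) {
  vapply(x, function(v) {
    s <- sign(v)
    if (v == 0) return(0)
    s * 2 / sqrt(pi) * stats::integrate(function(t) exp(-t^2), 0, abs(v),
                                        rel.tol = 1e-13)$value
  }, numeric(1))
}

# Eq.-style topology similarity by explicit token counting
oracle_ts <- function(qs, ts) {
  collapse <- function(s) {
    ch <- strsplit(s, "")[[1]]
    out <- ch[1]
    for (k in seq_along(ch)[-1]) if (ch[k] != ch[k - 1]) out <- c(out, ch[k])
    out
  }
  a <- collapse(qs)
  b <- collapse(ts)
  if (sum(a == "M") != sum(b == "M")) return(0)
  if (length(a) != length(b)) return(0)
  if (any((a == "M") != (b == "M"))) return(0)
  n11 <- n22 <- n12 <- n21 <- 0
  nrr <- 0
  other <- 0
  for (k in seq_along(a)) {
    if (a[k] == "M") next
    if (a[k] == "1" && b[k] == "1") n11 <- n11 + 1
    else if (a[k] == "2" && b[k] == "2") n22 <- n22 + 1
    else if (a[k] == "1" && b[k] == "2") n12 <- n12 + 1
    else if (a[k] == "2" && b[k] == "1") n21 <- n21 + 1
    else if (a[k] == "R" && b[k] == "R") nrr <- nrr + 1
    else other <- other + 1
  }
  L <- length(a)
  nm <- sum(a == "M")
  max(n11 + n22 + nrr, n12 + n21 + nrr) / (L - nm)
}

# exhaustive threading scan with naive mapping construction and energy
# accumulation by plain loops
oracle_best_energy <- function(query, template, potential, flank = 10L) {
  qs <- query$membrane_segments
  ts <- template$membrane_segments
  ntm <- nrow(qs)
  shift_sets <- lapply(seq_len(ntm), function(i) {
    lq <- qs$end[i] - qs$start[i] + 1L
    lt <- ts$end[i] - ts$start[i] + 1L
    floor((lt - lq) / 2) + (-2:2)
  })
  combos <- as.matrix(do.call(expand.grid, shift_sets))
  res <- template$residues
  n_t <- nrow(res)
  n_q <- nchar(query$sequence)
  coords <- as.matrix(res[, c("x", "y", "z")])
  pairs <- oracle_pair_contacts(template) # 0-based
  ic <- oracle_interchain(template)
  lip <- lipid_exposed(template) # SASA routine cross-checked elsewhere
  q_is_m <- strsplit(query$topology, "")[[1]] == "M"
  eps <- potential$epsilon
  h <- potential$h
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    sh <- combos[r, ]
    t2q <- rep(NA_integer_, n_t)
    qtaken <- rep(FALSE, n_q)
    anch <- matrix(0L, ntm, 4)
    for (i in seq_len(ntm)) {
      for (k in 0:(qs$end[i] - qs$start[i])) {
        tp <- ts$start[i] + sh[i] + k + 1L
        qp <- qs$start[i] + k + 1L
        if (tp >= 1 && tp <= n_t && is.na(t2q[tp])) {
          t2q[tp] <- qp
          qtaken[qp] <- TRUE
        }
      }
      anch[i, ] <- c(qs$start[i] + 1L, qs$end[i] + 1L,
                     ts$start[i] + sh[i] + 1L,
                     ts$start[i] + sh[i] + (qs$end[i] - qs$start[i]) + 1L)
    }
    up <- rep(TRUE, ntm)
    dn <- rep(TRUE, ntm)
    for (d in seq_len(flank)) {
      for (i in seq_len(ntm)) {
        if (up[i]) {
          qp <- anch[i, 1] - d
          tp <- anch[i, 3] - d
          if (qp < 1 || tp < 1 || q_is_m[qp] || qtaken[qp] || !is.na(t2q[tp])) {
            up[i] <- FALSE
          } else {
            t2q[tp] <- qp
            qtaken[qp] <- TRUE
          }
        }
        if (dn[i]) {
          qp <- anch[i, 2] + d
          tp <- anch[i, 4] + d
          if (qp > n_q || tp > n_t || q_is_m[qp] || qtaken[qp] || !is.na(t2q[tp])) {
            dn[i] <- FALSE
          } else {
            t2q[tp] <- qp
            qtaken[qp] <- TRUE
          }
        }
      }
    }
    e_rows <- numeric(query$msa$M)
    for (m in seq_len(query$msa$M)) {
      row <- query$msa$seqs[m, ]
      tot <- 0
      if (!is.null(pairs)) {
        for (pr in seq_len(nrow(pairs))) {
          ta <- pairs[pr, 1] + 1L
          tb <- pairs[pr, 2] + 1L
          if (!is.na(t2q[ta]) && !is.na(t2q[tb])) {
            aa <- row[t2q[ta]]
            bb <- row[t2q[tb]]
            if (aa %in% AA_ALPHABET && bb %in% AA_ALPHABET) {
              tot <- tot + eps[aa, bb]
            }
          }
        }
      }
      if (!is.null(ic)) {
        for (pr in seq_len(nrow(ic))) {
          ta <- ic[pr, 1] + 1L
          tb <- ic[pr, 2] + 1L
          if (!is.na(t2q[ta]) && !is.na(t2q[tb])) {
            aa <- row[t2q[ta]]
            bb <- row[t2q[tb]]
            if (aa %in% AA_ALPHABET && bb %in% AA_ALPHABET) {
              tot <- tot + eps[aa, bb]
            }
          }
        }
      }
      for (tp in lip + 1L) {
        if (!is.na(t2q[tp])) {
          aa <- row[t2q[tp]]
          if (aa %in% AA_ALPHABET) tot <- tot + h[aa]
        }
      }
      e_rows[m] <- tot
    }
    best <- min(best, mean(e_rows))
  }
  best
}
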