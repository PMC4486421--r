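#' Query object for threading
#'
#' Bundles a query sequence, its per-residue topology and an optional
#' multiple sequence alignment (already indexed to ungapped query
#' positions, query row first). Without an MSA the profile is the single
#' query sequence, in which case the profile energy reduces to the
#' single-sequence energy.
#'
#' @param sequence amino-acid string.
#' @param topology region string over `1`, `2`, `M`, `R`, same length.
#' @param msa optional `tmf_msa` (see [read_msa()], [msa_profile()]).
#' @return A `tmf_query` with fields `sequence`, `topology`, `msa`,
#'   `membrane_segments` (tibble `start`,`end`, 0-based inclusive),
#'   `grammar`.
#' @export
tmf_query <- function(sequence, topology, msa = NULL) {
  aa <- seq_chars(sequence)
  labs <- seq_chars(topology)
  if (length(labs) != length(aa)) {
    abort("topology length does not match sequence length")
  }
  if (is.null(msa)) msa <- msa_profile(paste(aa, collapse = ""))
  if (!inherits(msa, "tmf_msa")) abort("msa must be a tmf_msa")
  if (ncol(msa$seqs) != length(aa)) {
    abort("MSA columns do not match query length")
  }
  segs <- label_runs(labs)
  msegs <- segs[segs$label == "M", c("start", "end")]
  if (nrow(msegs) < 1L) abort("query must contain at least one membrane segment")
  structure(
    list(
      sequence = paste(aa, collapse = ""),
      topology = paste(labs, collapse = ""),
      msa = msa,
      membrane_segments = as_tibble(msegs),
      grammar = to_grammar(paste(labs, collapse = ""))
    ),
    class = "tmf_query"
  )
}

#' @export
print.tmf_query <- function(x, ...) {
  cat(sprintf("<tmf_query> %d residues, %d membrane segment(s), M = %d\n",
              nchar(x$sequence), nrow(x$membrane_segments), x$msa$M))
  invisible(x)
}

#' Enumerate gapless alignments of membrane segments
#'
#' For segment i with template length `L_str` and query length `L_qry`,
#' the allowed shifts of the query segment start relative to the template
#' segment start are `c_i - 2 .. c_i + 2` with
#' `c_i = floor((L_str - L_qry) / 2)` (floor division for odd
#' differences). The full Cartesian product over segments gives exactly
#' `5^NTM` candidate alignments; the last segment's shift varies fastest.
#'
#' @param query_segments,template_segments integer vectors of per-segment
#'   residue lengths (equal length).
#' @return Integer matrix, one row per alignment, one column per segment;
#'   attribute `centers` holds the `c_i`.
#' @export
enumerate_alignments <- function(query_segments, template_segments) {
  if (length(query_segments) != length(template_segments)) {
    abort("query and template segment counts differ")
  }
  ntm <- length(query_segments)
  centers <- floor((template_segments - query_segments) / 2)
  grids <- lapply(rev(seq_len(ntm)), function(i) centers[i] + (-2:2))
  g <- do.call(expand.grid, grids)          # first listed factor varies fastest
  shifts <- as.matrix(g[, rev(seq_len(ntm)), drop = FALSE])
  dimnames(shifts) <- NULL
  storage.mode(shifts) <- "integer"
  attr(shifts, "centers") <- as.integer(centers)
  shifts
}

#' Map query positions onto template positions for one alignment
#'
#' Builds the gapless mapping of one shift vector: within membrane
#' segment i the query residues occupy consecutive template positions
#' starting at `template_start + shift_i`; then up to `flank_length`
#' query residues upstream and downstream of each membrane segment fill
#' the template positions flanking the aligned stretch, so loop residues
#' of the template do not sit void. Flanks are truncated at either
#' chain's termini and stop at the first already-assigned position; when
#' the flanks of adjacent segments compete, the position nearer to its
#' segment wins (ties go to the earlier segment). Membrane residues never
#' serve as another segment's flank. Template positions left unfilled
#' contribute no energy terms.
#'
#' @param shifts integer shift vector (one per membrane segment).
#' @param query a `tmf_query`.
#' @param template a `tmf_structure`.
#' @param flank_length residues appended on each side (default 10).
#' @return Integer vector over template positions (1-based internally):
#'   entry t is the 1-based query position mapped there, or `NA`.
#' @export
apply_flanks <- function(shifts, query, template, flank_length = 10L) {
  qsegs <- query$membrane_segments
  tsegs <- template$membrane_segments
  ntm <- nrow(qsegs)
  stopifnot(length(shifts) == ntm, nrow(tsegs) == ntm)
  n_t <- nrow(template$residues)
  n_q <- nchar(query$sequence)
  t2q <- rep(NA_integer_, n_t)
  q_used <- rep(FALSE, n_q)
  q_is_m <- seq_chars(query$topology) == "M"
  # core segments first
  anchors <- matrix(0L, ntm, 4) # q_start, q_end, t_start_mapped, t_end_mapped
  for (i in seq_len(ntm)) {
    qs <- qsegs$start[i]; qe <- qsegs$end[i]
    ts <- tsegs$start[i] + shifts[i]
    for (k in 0:(qe - qs)) {
      tp <- ts + k + 1L
      qp <- qs + k + 1L
      if (tp >= 1L && tp <= n_t && is.na(t2q[tp])) {
        t2q[tp] <- qp
        q_used[qp] <- TRUE
      }
    }
    anchors[i, ] <- c(qs + 1L, qe + 1L, ts + 1L, ts + (qe - qs) + 1L)
  }
  # flanks, nearest-first so the closer segment wins contested positions
  up_open <- rep(TRUE, ntm)
  down_open <- rep(TRUE, ntm)
  for (d in seq_len(flank_length)) {
    for (i in seq_len(ntm)) {
      if (up_open[i]) {
        qp <- anchors[i, 1] - d
        tp <- anchors[i, 3] - d
        if (qp < 1L || tp < 1L || q_is_m[qp] || q_used[qp] || !is.na(t2q[tp])) {
          up_open[i] <- FALSE
        } else {
          t2q[tp] <- qp
          q_used[qp] <- TRUE
        }
      }
      if (down_open[i]) {
        qp <- anchors[i, 2] + d
        tp <- anchors[i, 4] + d
        if (qp > n_q || tp > n_t || q_is_m[qp] || q_used[qp] || !is.na(t2q[tp])) {
          down_open[i] <- FALSE
        } else {
          t2q[tp] <- qp
          q_used[qp] <- TRUE
        }
      }
    }
  }
  t2q
}

# everything about a template that does not depend on the query
template_scoring_context <- function(template, potential, zdist = NULL) {
  geom <- structure_contact_geometry(template)
  const <- 0
  hetero <- NULL
  if (!is.null(template$neighbor_centers) &&
      nrow(template$neighbor_centers) > 0L) {
    if (is.null(zdist)) {
      abort("template has unknown-identity neighbors; a z-distribution is required")
    }
    eps_exp <- zdist$freq %*% potential$epsilon # layer x aa expectation
    nb <- as.matrix(template$neighbor_centers[, c("x", "y", "z")])
    cen <- as.matrix(template$residues[, c("x", "y", "z")])
    d2 <- outer(rowSums(cen^2), rowSums(nb^2), "+") - 2 * cen %*% t(nb)
    hit <- which(d2 < 25, arr.ind = TRUE)
    layer <- zdist_layer(zdist, nb[, 3])
    ok <- !is.na(layer[hit[, 2]])
    hetero <- list(pos = hit[ok, 1], layer = layer[hit[ok, 2]], eps_exp = eps_exp)
    # neighbor-neighbor pairs: double expectation, constant per template
    if (nrow(nb) >= 2L) {
      dn <- as.matrix(stats::dist(nb))
      nn <- which(dn < 5 & upper.tri(dn), arr.ind = TRUE)
      for (r in seq_len(nrow(nn))) {
        l1 <- layer[nn[r, 1]]; l2 <- layer[nn[r, 2]]
        if (!is.na(l1) && !is.na(l2)) {
          const <- const +
            as.numeric(zdist$freq[l1, ] %*% potential$epsilon %*% zdist$freq[l2, ])
        }
      }
    }
  }
  list(geom = geom, hetero = hetero, const = const)
}

alignment_energy <- function(t2q, query, ctx, potential) {
  msa <- query$msa
  eps <- potential$epsilon
  h <- potential$h
  geom <- ctx$geom
  e <- vapply(seq_len(msa$M), function(k) {
    ai_q <- aa_index(msa$seqs[k, ])
    ai_t <- rep(NA_integer_, length(t2q))
    mapped <- !is.na(t2q)
    ai_t[mapped] <- ai_q[t2q[mapped]]
    val <- assignment_energy(ai_t, geom$pair_a, geom$pair_b, geom$lipid, eps, h)
    if (!is.null(ctx$hetero)) {
      aa_at <- ai_t[ctx$hetero$pos]
      ok <- !is.na(aa_at)
      if (any(ok)) {
        val <- val + sum(ctx$hetero$eps_exp[cbind(ctx$hetero$layer[ok], aa_at[ok])])
      }
    }
    val
  }, numeric(1))
  mean(e) + ctx$const
}

#' Score a query against one template
#'
#' Enumerates all `5^NTM` gapless alignments of the query's membrane
#' segments onto the template's (plus 10-residue flanks), evaluates the
#' profile energy of each against the statistical potential -- intra-chain
#' contacts, homo-oligomer symmetry-image contacts, lipid terms at mapped
#' exposed positions, and z-layer expectation terms for unknown-identity
#' hetero-oligomer neighbors -- and returns the minimum-energy alignment.
#' Ties go to the first enumerated alignment.
#'
#' @param query a [tmf_query()].
#' @param template a `tmf_structure` (should already have passed topology
#'   filtering).
#' @param potential a `tmf_potential`.
#' @param zdist a `tmf_zdist`; required when the template carries
#'   unknown-identity neighbor centers.
#' @param flank_length flank residues per side (default 10).
#' @return List with `shifts` (best shift vector), `energy` (its profile
#'   energy), `mapping` (template-to-query vector from [apply_flanks()]),
#'   and attribute-free vector `energies` of all enumerated alignments in
#'   enumeration order.
#' @export
score_template <- function(query, template, potential, zdist = NULL,
                           flank_length = 10L) {
  qsegs <- query$membrane_segments
  tsegs <- template$membrane_segments
  if (nrow(qsegs) != nrow(tsegs)) {
    abort("query and template have different numbers of membrane segments")
  }
  shifts <- enumerate_alignments(
    qsegs$end - qsegs$start + 1L,
    tsegs$end - tsegs$start + 1L
  )
  ctx <- template_scoring_context(template, potential, zdist)
  energies <- vapply(seq_len(nrow(shifts)), function(r) {
    t2q <- apply_flanks(shifts[r, ], query, template, flank_length)
    alignment_energy(t2q, query, ctx, potential)
  }, numeric(1))
  best <- which.min(energies) # which.min returns the first minimum
  list(
    shifts = shifts[best, ],
    energy = energies[best],
    mapping = apply_flanks(shifts[best, ], query, template, flank_length),
    energies = energies
  )
}

#' Rank a template library for a query
#'
#' Scores every template with [score_template()] and ranks by best
#' alignment energy, lowest first; the rank-1 template is the predicted
#' fold. Ties are broken by template identifier (lexicographic). Each
#' entry carries the reduced energy `e = E/NTM` and its
#' reliability-of-nativeness score.
#'
#' @param query a [tmf_query()].
#' @param library named list of `tmf_structure` templates (normally the
#'   output of topology filtering).
#' @param potential a `tmf_potential`.
#' @param zdist optional `tmf_zdist`.
#' @param reliability a [reliability_model()] used for the score column.
#' @param flank_length flank residues per side.
#' @return A `tmf_ranking` tibble with columns `template_id`, `rank`,
#'   `energy`, `reduced_energy`, `reliability`, `shifts`
#'   (comma-separated), `ts` (topology similarity to the query). Zero
#'   rows (with attribute `no_compatible_fold = TRUE`) when the library
#'   is empty.
#' @export
rank_library <- function(query, library, potential, zdist = NULL,
                         reliability = default_reliability_model(),
                         flank_length = 10L) {
  empty <- tibble(
    template_id = character(), rank = integer(), energy = numeric(),
    reduced_energy = numeric(), reliability = numeric(),
    shifts = character(), ts = numeric()
  )
  if (length(library) == 0L) {
    attr(empty, "no_compatible_fold") <- TRUE
    class(empty) <- c("tmf_ranking", class(empty))
    return(empty)
  }
  ids <- names(library)
  if (is.null(ids)) ids <- as.character(seq_along(library))
  rows <- vector("list", length(library))
  for (i in seq_along(library)) {
    tpl <- library[[i]]
    sc <- score_template(query, tpl, potential, zdist, flank_length)
    ntm <- n_tm(tpl)
    e_red <- reduced_energy(sc$energy, ntm)
    rows[[i]] <- tibble(
      template_id = ids[i],
      energy = sc$energy,
      reduced_energy = e_red,
      reliability = reliability_score(e_red, reliability),
      shifts = paste(sc$shifts, collapse = ","),
      ts = topology_similarity(query$grammar, to_grammar(tpl$topology))
    )
  }
  out <- bind_rows(rows) |>
    arrange(.data$energy, .data$template_id) |>
    mutate(rank = row_number()) |>
    select("template_id", "rank", "energy", "reduced_energy",
           "reliability", "shifts", "ts")
  class(out) <- c("tmf_ranking", class(out))
  out
}

#' Accuracy of a random fold predictor
#'
#' With `F` distinct fold classes compatible with the query (same number
#' of membrane segments), a uniform random predictor is right with
#' probability `1/F`.
#'
#' @param fold_classes either a single count `F >= 1` or a vector of fold
#'   class labels whose distinct values are counted.
#' @return `1/F`.
#' @export
random_baseline <- function(fold_classes) {
  f <- if (length(fold_classes) == 1L && is.numeric(fold_classes)) {
    as.integer(fold_classes)
  } else {
    length(unique(fold_classes))
  }
  if (is.na(f) || f < 1L) abort("need at least one fold class")
  1 / f
}

#' Plot a template ranking
#'
#' @param object a `tmf_ranking` from [rank_library()].
#' @param ... unused.
#' @return A ggplot object: energy per template in rank order, colored by
#'   reliability.
#' @exportS3Method ggplot2::autoplot
autoplot.tmf_ranking <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$template_id, .data$rank),
    y = .data$energy, fill = .data$reliability
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "template (rank order)", y = "threading energy E") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
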