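#' Chain structure container
#'
#' A `tmf_structure` holds one transmembrane chain in the membrane frame:
#' the membrane normal is the z axis and the membrane core is at z = 0.
#' Residues are stored 0-based and contiguous (the numbering that remains
#' after non-membrane parts of the source structure were cut away); any
#' original author numbering is metadata only.
#'
#' @param chain_id single string identifying the chain/template.
#' @param residues tibble with columns `index` (0-based integer), `aa`
#'   (one-letter code, nonstandard residues as `"X"`), `x`, `y`, `z`
#'   (interaction-center coordinates in Angstrom: the C-beta atom, or
#'   C-alpha for glycine).
#' @param atoms tibble of heavy atoms with columns `res_index`, `name`,
#'   `x`, `y`, `z`. May be minimal (interaction centers only).
#' @param topology per-residue region string over the alphabet `1` (side
#'   one), `2` (side two), `M` (membrane), `R` (re-entrant); same length
#'   as `residues`.
#' @param symmetry_ops list of 3x4 rigid-transform matrices (rotation |
#'   translation) describing the homo-oligomeric assembly; the identity
#'   operator is always present (and added if missing).
#' @param half_thickness membrane half thickness in Angstrom.
#' @param neighbor_centers optional tibble (`x`, `y`, `z`) of interaction
#'   centers of surrounding chains whose residue identities are unknown
#'   (hetero-oligomer partners); used via the z-layer amino-acid
#'   distribution at scoring time.
#' @param z_tolerance slack (Angstrom) allowed when checking that
#'   membrane-labelled residues sit inside the slab.
#'
#' @return An object of class `tmf_structure` with fields `chain_id`,
#'   `residues`, `atoms`, `topology`, `membrane_segments` (tibble of
#'   0-based `start`,`end`, inclusive), `symmetry_ops`, `half_thickness`,
#'   `neighbor_centers`.
#' @export
chain_structure <- function(chain_id, residues, topology,
                            atoms = NULL,
                            symmetry_ops = list(),
                            half_thickness = 15,
                            neighbor_centers = NULL,
                            z_tolerance = 1.0) {
  residues <- as_tibble(residues)
  stopifnot(all(c("index", "aa", "x", "y", "z") %in% names(residues)))
  n <- nrow(residues)
  if (n == 0L) abort("chain has no residues")
  if (any(diff(residues$index) <= 0L)) {
    abort("residue indices must be strictly increasing")
  }
  labs <- seq_chars(topology)
  if (length(labs) != n) {
    abort(sprintf(
      "region string length (%d) does not match residue count (%d)",
      length(labs), n
    ))
  }
  bad <- setdiff(unique(labs), c("1", "2", "M", "R"))
  if (length(bad) > 0L) {
    abort(paste0("unknown region label(s): ", paste(bad, collapse = ", ")))
  }
  segs <- label_runs(labs)
  msegs <- segs[segs$label == "M", c("start", "end")]
  if (nrow(msegs) < 1L) abort("chain must contain at least one membrane segment")
  # membrane residues must lie inside the slab (interaction-center z)
  in_m <- labs == "M"
  zoff <- abs(residues$z[in_m]) - (half_thickness + z_tolerance)
  if (any(zoff > 0)) {
    abort(sprintf(
      "%d membrane-labelled residue(s) lie outside the slab (max overshoot %.2f A)",
      sum(zoff > 0), max(zoff)
    ))
  }
  ops <- normalize_symmetry_ops(symmetry_ops)
  if (is.null(atoms)) {
    atoms <- tibble(
      res_index = residues$index, name = "CB",
      x = residues$x, y = residues$y, z = residues$z
    )
  }
  if (!is.null(neighbor_centers)) {
    neighbor_centers <- as_tibble(neighbor_centers)
    stopifnot(all(c("x", "y", "z") %in% names(neighbor_centers)))
  }
  structure(
    list(
      chain_id = as.character(chain_id),
      residues = residues,
      atoms = as_tibble(atoms),
      topology = paste(labs, collapse = ""),
      membrane_segments = as_tibble(msegs),
      symmetry_ops = ops,
      half_thickness = half_thickness,
      neighbor_centers = neighbor_centers
    ),
    class = "tmf_structure"
  )
}

# runs of identical labels -> tibble(label, start, end) in 0-based indices
label_runs <- function(labs) {
  r <- rle(labs)
  end <- cumsum(r$lengths) - 1L
  start <- end - r$lengths + 1L
  tibble(label = r$values, start = start, end = end)
}

normalize_symmetry_ops <- function(ops) {
  ident <- cbind(diag(3), c(0, 0, 0))
  ops <- lapply(ops, function(m) {
    m <- matrix(as.numeric(m), nrow = 3, ncol = 4)
    rot <- m[, 1:3]
    if (abs(abs(det(rot)) - 1) > 1e-6 ||
        max(abs(crossprod(rot) - diag(3))) > 1e-6) {
      abort("symmetry operator is not a rigid transform")
    }
    m
  })
  is_ident <- vapply(ops, function(m) max(abs(m - ident)) < 1e-9, logical(1))
  c(list(ident), ops[!is_ident])
}

#' @export
print.tmf_structure <- function(x, ...) {
  cat(sprintf(
    "<tmf_structure> %s: %d residues, %d membrane segment(s), %d symmetry op(s)\n",
    x$chain_id, nrow(x$residues), nrow(x$membrane_segments),
    length(x$symmetry_ops)
  ))
  invisible(x)
}

#' Number of transmembrane segments of a chain
#' @param structure a `tmf_structure`.
#' @return Integer count of membrane segments (NTM).
#' @export
n_tm <- function(structure) nrow(structure$membrane_segments)

three_letter <- function(aa) {
  tbl <- setNames(bio3d::aa.table$aa3, bio3d::aa.table$aa1)
  out <- tbl[aa]
  out[is.na(out)] <- "UNK"
  unname(out)
}

#' Read a template chain from a PDB file plus a region annotation file
#'
#' The PDB file supplies heavy-atom coordinates already in the membrane
#' frame (z axis = membrane normal, core at z = 0). The region file is a
#' two-column TSV (0-based residue index, region label) with `#`-prefixed
#' header lines carrying the membrane half thickness, optional symmetry
#' operators and optional unknown-identity neighbor centers (see
#' [write_template()] for the exact layout).
#'
#' The interaction center of a residue is its C-beta atom; glycine uses
#' C-alpha. A non-glycine residue lacking C-beta falls back to C-alpha
#' with a warning; a residue with neither is an error.
#'
#' @param structure_file path to a PDB file.
#' @param region_file path to the region annotation TSV.
#' @return A validated [chain_structure()].
#' @export
read_template <- function(structure_file, region_file) {
  if (!file.exists(structure_file)) abort(paste0("no such file: ", structure_file))
  if (!file.exists(region_file)) abort(paste0("no such file: ", region_file))
  pdb <- tryCatch(
    bio3d::read.pdb(structure_file, verbose = FALSE),
    error = function(e) abort(paste0("malformed PDB: ", conditionMessage(e)))
  )
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) abort("malformed PDB: no ATOM records")
  # keep heavy atoms only
  at <- at[!at$elety %in% c("H") & !grepl("^[0-9]*H", at$elety), , drop = FALSE]
  key <- paste(at$chain, at$resno, at$insert)
  ord <- unique(key)
  reg <- read_region_file(region_file)
  if (length(ord) != nrow(reg$labels)) {
    abort(sprintf(
      "region string length (%d) does not match residue count (%d)",
      nrow(reg$labels), length(ord)
    ))
  }
  res_rows <- vector("list", length(ord))
  atom_rows <- vector("list", length(ord))
  for (i in seq_along(ord)) {
    sub <- at[key == ord[i], , drop = FALSE]
    aa1 <- suppressWarnings(bio3d::aa321(sub$resid[1]))
    if (is.na(aa1) || !aa1 %in% AA_ALPHABET) aa1 <- "X"
    cb <- sub[sub$elety == "CB", , drop = FALSE]
    ca <- sub[sub$elety == "CA", , drop = FALSE]
    if (aa1 == "G" || nrow(cb) == 0L) {
      if (nrow(ca) == 0L && nrow(cb) == 0L) {
        abort(sprintf("residue %d has no interaction-center atom (CB/CA)", i - 1L))
      }
      if (aa1 != "G" && nrow(cb) == 0L) {
        warn(sprintf("residue %d (%s) lacks CB; using CA as interaction center",
                     i - 1L, aa1))
      }
      cen <- if (nrow(ca) > 0L) ca[1, ] else cb[1, ]
    } else {
      cen <- cb[1, ]
    }
    res_rows[[i]] <- tibble(
      index = i - 1L, aa = aa1,
      x = cen$x, y = cen$y, z = cen$z,
      author_resno = sub$resno[1]
    )
    atom_rows[[i]] <- tibble(
      res_index = i - 1L, name = sub$elety,
      x = sub$x, y = sub$y, z = sub$z
    )
  }
  chain_structure(
    chain_id = reg$chain_id %||% at$chain[1] %||% "A",
    residues = bind_rows(res_rows),
    atoms = bind_rows(atom_rows),
    topology = reg$labels$label,
    symmetry_ops = reg$symmetry_ops,
    half_thickness = reg$half_thickness,
    neighbor_centers = reg$neighbor_centers
  )
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1])) b else a

read_region_file <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  get1 <- function(tag) {
    hit <- hdr[startsWith(hdr, paste0("#", tag, "\t"))]
    if (length(hit) == 0L) return(NULL)
    strsplit(hit[[1]], "\t")[[1]][-1]
  }
  half <- get1("half_thickness")
  half <- if (is.null(half)) 15 else as.numeric(half[1])
  cid <- get1("chain_id")
  ops <- lapply(
    hdr[startsWith(hdr, "#symmetry_op\t")],
    function(l) {
      v <- as.numeric(strsplit(l, "\t")[[1]][-1])
      if (length(v) != 12L || anyNA(v)) abort("symmetry_op header needs 12 numbers")
      matrix(v, nrow = 3, byrow = TRUE)
    }
  )
  nb <- hdr[startsWith(hdr, "#neighbor\t")]
  neighbor_centers <- NULL
  if (length(nb) > 0L) {
    m <- do.call(rbind, lapply(nb, function(l) as.numeric(strsplit(l, "\t")[[1]][-1])))
    if (ncol(m) != 3L || anyNA(m)) abort("neighbor header needs 3 numbers per line")
    neighbor_centers <- tibble(x = m[, 1], y = m[, 2], z = m[, 3])
  }
  parts <- strsplit(body, "\t")
  if (any(lengths(parts) < 2L)) abort("region file rows need 2 tab-separated columns")
  labels <- tibble(
    index = as.integer(vapply(parts, `[`, "", 1L)),
    label = vapply(parts, `[`, "", 2L)
  )
  if (anyNA(labels$index)) abort("non-integer residue index in region file")
  list(
    chain_id = if (is.null(cid)) NULL else cid[1],
    half_thickness = half,
    symmetry_ops = ops,
    neighbor_centers = neighbor_centers,
    labels = labels
  )
}

#' Write a template chain to PDB + region annotation files
#'
#' Inverse of [read_template()]: `read_template(write_template(x))` parses
#' to an equal structure (coordinates at PDB precision, 1e-3 Angstrom).
#'
#' @param structure a `tmf_structure`.
#' @param structure_file,region_file output paths.
#' @return Invisibly, the two paths.
#' @export
write_template <- function(structure, structure_file, region_file) {
  res <- structure$residues
  at <- structure$atoms
  aa3 <- three_letter(res$aa)
  names(aa3) <- as.character(res$index)
  bio3d::write.pdb(
    file = structure_file,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = at$res_index + 1L,
    resid = aa3[as.character(at$res_index)],
    elety = at$name,
    chain = substr(structure$chain_id, 1, 1)
  )
  hdr <- c(
    paste0("#chain_id\t", structure$chain_id),
    paste0("#half_thickness\t", format(structure$half_thickness)),
    vapply(
      structure$symmetry_ops[-1],
      function(m) paste0("#symmetry_op\t",
                         paste(format(as.numeric(t(m)), digits = 12), collapse = "\t")),
      character(1)
    )
  )
  if (!is.null(structure$neighbor_centers)) {
    hdr <- c(hdr, apply(structure$neighbor_centers, 1, function(r) {
      paste0("#neighbor\t", paste(format(as.numeric(r), digits = 12), collapse = "\t"))
    }))
  }
  labs <- seq_chars(structure$topology)
  writeLines(
    c(hdr, paste(res$index, labs, sep = "\t")),
    region_file
  )
  invisible(c(structure_file, region_file))
}

#' Read a query sequence from a FASTA file
#'
#' @param fasta_file path; the first record is used.
#' @return Single uppercase sequence string.
#' @export
read_query <- function(fasta_file) {
  ss <- Biostrings::readAAStringSet(fasta_file)
  if (length(ss) == 0L) abort("empty FASTA file")
  toupper(as.character(ss[[1]]))
}

#' Read a topology (region string) file
#'
#' One-line per-residue region string over the alphabet `1`, `2`, `M`, `R`.
#'
#' @param topo_file path.
#' @return Region string.
#' @export
read_topology <- function(topo_file) {
  lines <- trimws(readLines(topo_file))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, ">")]
  if (length(lines) == 0L) abort("empty topology file")
  paste(lines, collapse = "")
}

#' Read a multiple sequence alignment (aligned FASTA)
#'
#' The first record must be the query. Columns where the query has a gap
#' are removed, so the profile is indexed by ungapped query positions.
#' Rows covering less than `min_coverage` of the masked positions (all
#' positions when `membrane_mask` is `NULL`) are dropped; the query row is
#' always kept.
#'
#' @param msa_file aligned FASTA path.
#' @param membrane_mask optional logical vector over ungapped query
#'   positions marking membrane positions, used for the coverage filter.
#' @param min_coverage minimum fraction of non-gap characters per retained
#'   row (default 0.2).
#' @return A `tmf_msa`: list with `seqs` (M x L character matrix, query
#'   row first) and `M` (number of sequences).
#' @export
read_msa <- function(msa_file, membrane_mask = NULL, min_coverage = 0.2) {
  ss <- Biostrings::readAAStringSet(msa_file)
  if (length(ss) == 0L) abort("empty MSA file")
  w <- Biostrings::width(ss)
  if (length(unique(w)) != 1L) abort("ragged alignment: rows differ in length")
  mat <- do.call(rbind, strsplit(toupper(as.character(ss)), ""))
  keep_col <- !(mat[1, ] %in% c("-", "."))
  mat <- mat[, keep_col, drop = FALSE]
  mask <- if (is.null(membrane_mask)) rep(TRUE, ncol(mat)) else membrane_mask
  if (length(mask) != ncol(mat)) abort("membrane_mask length mismatch")
  cov <- rowMeans(matrix(!(mat[, mask, drop = FALSE] %in% c("-", ".")),
                         nrow = nrow(mat)))
  keep_row <- cov >= min_coverage
  keep_row[1] <- TRUE
  mat <- mat[keep_row, , drop = FALSE]
  msa_profile(mat)
}

#' Build an MSA profile from a character matrix or sequence strings
#'
#' @param seqs character matrix (rows = sequences, query first) or a
#'   character vector of equal-length sequence strings.
#' @return A `tmf_msa`.
#' @export
msa_profile <- function(seqs) {
  if (!is.matrix(seqs)) {
    seqs <- do.call(rbind, strsplit(toupper(seqs), ""))
  }
  if (any(seqs[1, ] %in% c("-", "."))) abort("query row must be gap-free")
  dimnames(seqs) <- NULL
  structure(list(seqs = seqs, M = nrow(seqs)), class = "tmf_msa")
}

#' @export
print.tmf_msa <- function(x, ...) {
  cat(sprintf("<tmf_msa> %d sequence(s) x %d position(s)\n", x$M, ncol(x$seqs)))
  invisible(x)
}
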