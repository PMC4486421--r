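#' Grammatical structure of a topology
#'
#' Collapses runs of identical per-residue region labels into single
#' tokens: `"11111MMMMM22222MMMMM22222MMMMM11111"` becomes `"1M2M2M1"`.
#' The grammar records the order of side changes; `L` is the token count
#' and `N_M` the number of membrane tokens.
#'
#' @param region_string per-residue region string over `1`, `2`, `M`, `R`.
#' @return A `tmf_grammar`: `tokens` (character vector), `L`, `N_M`,
#'   `run_lengths` (residue count per token, kept for the linker filter).
#' @export
to_grammar <- function(region_string) {
  labs <- seq_chars(region_string)
  labs <- labs[nzchar(labs)]
  if (length(labs) == 0L) abort("empty region string")
  bad <- setdiff(unique(labs), c("1", "2", "M", "R"))
  if (length(bad) > 0L) {
    abort(paste0("unknown region label(s): ", paste(bad, collapse = ", ")))
  }
  r <- rle(labs)
  structure(
    list(
      tokens = r$values,
      L = length(r$values),
      N_M = sum(r$values == "M"),
      run_lengths = r$lengths
    ),
    class = "tmf_grammar"
  )
}

#' @export
print.tmf_grammar <- function(x, ...) {
  cat(sprintf("<tmf_grammar> %s (L = %d, N_M = %d)\n",
              paste(x$tokens, collapse = ""), x$L, x$N_M))
  invisible(x)
}

#' @export
format.tmf_grammar <- function(x, ...) paste(x$tokens, collapse = "")

as_grammar <- function(x) {
  if (inherits(x, "tmf_grammar")) x else to_grammar(x)
}

# pad a grammar that starts/ends with M with a terminal wildcard so the
# token frame is always side M side M ... side; wildcards match anything
# and are excluded from both numerator and denominator
padded_tokens <- function(g) {
  tok <- g$tokens
  if (tok[1] == "M") tok <- c("*", tok)
  if (tok[length(tok)] == "M") tok <- c(tok, "*")
  tok
}

#' Topology similarity (TS) between two grammars
#'
#' Positional comparison of the non-membrane tokens of two grammatical
#' structures with equal numbers of membrane regions:
#' `TS = max(N_11 + N_22, N_12 + N_21) / (L - N_M)`, where `N_11`/`N_22`
#' count matching side assignments and `N_12`/`N_21` opposite ones. The
#' maximum over the direct and the globally side-swapped comparison makes
#' the score invariant to the arbitrary side labelling of the annotation
#' databases. Re-entrant tokens form a third class that matches only
#' itself. Grammars with differing `N_M` or incompatible token frames are
#' incompatible and score 0; a missing terminal side token (grammar
#' starting or ending with `M`) is a wildcard excluded from the count.
#'
#' @param query,template `tmf_grammar` objects or region strings.
#' @return TS in `[0, 1]`.
#' @export
topology_similarity <- function(query, template) {
  q <- as_grammar(query)
  t <- as_grammar(template)
  if (q$N_M != t$N_M) return(0)
  qt <- padded_tokens(q)
  tt <- padded_tokens(t)
  if (length(qt) != length(tt)) return(0)
  if (!identical(qt == "M", tt == "M")) return(0)
  side <- qt != "M"
  a <- qt[side]
  b <- tt[side]
  counted <- a != "*" & b != "*"
  if (!any(counted)) return(1)
  a <- a[counted]
  b <- b[counted]
  swap <- c(`1` = "2", `2` = "1", R = "R")
  direct <- sum(a == b)
  inverted <- sum(a == unname(swap[b]))
  max(direct, inverted) / length(a)
}

grammar_has_reentrant <- function(g) any(as_grammar(g)$tokens == "R")

#' Filter a template library by topology compatibility
#'
#' Keeps templates whose grammar has the same number of membrane segments
#' as the query and a topology similarity strictly greater than
#' `threshold`. When the query grammar has no re-entrant token, templates
#' with re-entrant regions are rejected regardless of TS.
#'
#' @param query query grammar or region string.
#' @param library list of template grammars/region strings (named, or
#'   items carrying a `grammar` field).
#' @param threshold TS acceptance threshold (default 0.9, strict).
#' @return The accepted sublist, with a `screen` attribute holding the
#'   per-template tibble from [topology_screen()].
#' @export
filter_templates <- function(query, library, threshold = 0.9) {
  scr <- topology_screen(query, library, threshold)
  out <- library[scr$accepted]
  attr(out, "screen") <- scr
  out
}

#' @rdname filter_templates
#' @return `topology_screen`: tibble with `template_id`, `ts`,
#'   `ntm_match`, `reentrant_ok`, `accepted`.
#' @export
topology_screen <- function(query, library, threshold = 0.9) {
  q <- as_grammar(query)
  ids <- names(library)
  if (is.null(ids)) ids <- as.character(seq_along(library))
  grams <- lapply(library, function(item) {
    if (is.list(item) && !inherits(item, "tmf_grammar") && !is.null(item$grammar)) {
      as_grammar(item$grammar)
    } else {
      as_grammar(item)
    }
  })
  ts <- unname(vapply(grams, function(g) topology_similarity(q, g), numeric(1)))
  ntm_match <- unname(vapply(grams, function(g) g$N_M == q$N_M, logical(1)))
  reentrant_ok <- if (grammar_has_reentrant(q)) {
    rep(TRUE, length(grams))
  } else {
    unname(!vapply(grams, grammar_has_reentrant, logical(1)))
  }
  tibble(
    template_id = ids,
    ts = ts,
    ntm_match = ntm_match,
    reentrant_ok = reentrant_ok,
    accepted = ntm_match & reentrant_ok & ts > threshold
  )
}

#' Optional short-linker filter
#'
#' Rejects a template when a short query linker (at most `short_cutoff`
#' residues between two membrane segments) would be aligned to a long
#' template loop (more than `long_cutoff` residues). Off by default in
#' the pipeline: applying it was not observed to change accuracy, which
#' may reflect an arbitrary short/long partition.
#'
#' @param query,template region strings (or `tmf_grammar`s built from
#'   them, which retain run lengths).
#' @param short_cutoff maximum length of a "short" query linker (5).
#' @param long_cutoff minimum length above which a template loop is
#'   "long" (15).
#' @return `TRUE` to accept, `FALSE` to reject.
#' @export
linker_length_filter <- function(query, template, short_cutoff = 5L,
                                 long_cutoff = 15L) {
  q <- as_grammar(query)
  t <- as_grammar(template)
  ql <- inter_m_linkers(q)
  tl <- inter_m_linkers(t)
  if (length(ql) != length(tl)) return(TRUE)
  !any(ql <= short_cutoff & tl > long_cutoff)
}

# residue lengths of the loops strictly between consecutive M tokens
inter_m_linkers <- function(g) {
  m_pos <- which(g$tokens == "M")
  if (length(m_pos) < 2L) return(integer())
  vapply(seq_len(length(m_pos) - 1L), function(i) {
    between <- seq(m_pos[i] + 1L, m_pos[i + 1L] - 1L)
    if (length(between) == 0L) 0L else sum(g$run_lengths[between])
  }, integer(1))
}
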