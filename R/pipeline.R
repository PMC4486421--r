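#' Assign fold classes to jackknife folds
#'
#' Partitions fold-class identifiers (not individual chains) into `k`
#' folds, so a held-out query's own structure never contributes to the
#' potential it is scored with.
#'
#' @param class_ids character vector of fold class / template identifiers.
#' @param k number of folds (capped at the number of classes).
#' @param seed integer seed for the shuffle.
#' @return Named integer vector: fold number per class id; every class
#'   appears exactly once.
#' @export
assign_folds <- function(class_ids, k = 10L, seed = 1L) {
  ids <- unique(class_ids)
  k <- min(as.integer(k), length(ids))
  shuffled <- withr_seed(seed, sample(ids))
  f <- setNames(rep(seq_len(k), length.out = length(ids)), shuffled)
  f[ids]
}

#' Assemble the training items of a library
#'
#' Every template contributes its native (structure, sequence) pair;
#' optionally the library's query sequences are added as further chains
#' threaded on their own native structures, which sharpens the
#' maximum-likelihood estimate the same way multiple chains per fold
#' class do in a real template set.
#'
#' @param lib a `tmf_library`.
#' @param include_queries add the query sequences (default TRUE).
#' @param class_ids restrict to these template ids (default all).
#' @return List of items consumable by [train_potential()].
#' @export
library_training_set <- function(lib, include_queries = TRUE,
                                 class_ids = names(lib$templates)) {
  items <- lapply(lib$templates[class_ids], function(s) list(structure = s))
  if (include_queries && nrow(lib$queries) > 0L) {
    qs <- lib$queries[lib$queries$native_template %in% class_ids, , drop = FALSE]
    items <- c(items, lapply(seq_len(nrow(qs)), function(i) {
      list(structure = lib$templates[[qs$native_template[i]]],
           sequence = qs$sequence[i])
    }))
  }
  unname(items)
}

#' Train the full model from a template library
#'
#' Trains the statistical potential on the library's (structure, native
#' sequence) pairs, builds the z-layer amino-acid distribution, and --
#' when `jackknife_k` is given -- runs a fold-class jackknife: for each
#' fold a potential is trained without the held-out classes, the held-out
#' queries are ranked against the full library, and the native and
#' best-decoy reduced energies collected over folds are fitted into a
#' reliability model.
#'
#' @param lib a `tmf_library` (see [make_library()], [load_library()]).
#' @param config a [training_config()].
#' @param jackknife_k folds over fold classes, or `NULL` to skip.
#' @param topology_filter apply [filter_templates()] before ranking
#'   held-out queries (default TRUE).
#' @param out_dir optional directory: writes `potential.tsv`,
#'   `zdist.tsv`, `reliability.json` and a `provenance.json` run record.
#' @return List with `potential`, `zdist`, `reliability` (fitted model,
#'   or the shipped default when the jackknife was skipped or too small
#'   to fit), `jackknife` (per-query tibble or NULL), `accuracy`.
#' @export
run_train <- function(lib, config = training_config(), jackknife_k = NULL,
                      topology_filter = TRUE, out_dir = NULL) {
  if (length(lib$templates) < 1L) abort("library has no templates")
  potential <- train_potential(library_training_set(lib), config)
  zdist <- build_z_distribution(lib$templates)

  reliability <- default_reliability_model()
  jk <- NULL
  accuracy <- NA_real_
  if (!is.null(jackknife_k)) {
    folds <- assign_folds(names(lib$templates), jackknife_k, config$rng_seed)
    rows <- list()
    for (f in sort(unique(folds))) {
      held <- names(folds)[folds == f]
      train_ids <- setdiff(names(lib$templates), held)
      if (length(train_ids) == 0L) next
      pot_f <- train_potential(
        library_training_set(lib, class_ids = train_ids), config
      )
      qs <- lib$queries[lib$queries$native_template %in% held, , drop = FALSE]
      for (i in seq_len(nrow(qs))) {
        q <- qs[i, ]
        res <- run_predict(
          tmf_query(q$sequence, q$topology),
          lib$templates, pot_f, zdist,
          reliability = default_reliability_model(),
          topology_filter = topology_filter
        )
        rk <- res$ranking
        if (nrow(rk) == 0L) next
        nat <- rk[rk$template_id == q$native_template, , drop = FALSE]
        dec <- rk[rk$template_id != q$native_template, , drop = FALSE]
        rows[[length(rows) + 1L]] <- tibble(
          query_id = q$query_id,
          fold = f,
          native_template = q$native_template,
          predicted = rk$template_id[1],
          correct = rk$template_id[1] == q$native_template,
          native_e = if (nrow(nat) > 0) nat$reduced_energy[1] else NA_real_,
          decoy_e = if (nrow(dec) > 0) min(dec$reduced_energy) else NA_real_
        )
      }
    }
    jk <- bind_rows(rows)
    if (nrow(jk) > 0L) {
      accuracy <- mean(jk$correct)
      ne <- jk$native_e[!is.na(jk$native_e)]
      de <- jk$decoy_e[!is.na(jk$decoy_e)]
      if (length(ne) >= 10L && length(de) >= 10L &&
          diff(range(ne)) > 1e-8 && diff(range(de)) > 1e-8) {
        reliability <- fit_curves(ne, de)
      }
    }
  }

  out <- list(potential = potential, zdist = zdist, reliability = reliability,
              jackknife = jk, accuracy = accuracy)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_potential(potential, file.path(out_dir, "potential.tsv"))
    write_z_distribution(zdist, file.path(out_dir, "zdist.tsv"))
    write_reliability_model(reliability, file.path(out_dir, "reliability.json"))
    jsonlite::write_json(
      list(
        config = unclass(config),
        n_templates = length(lib$templates),
        n_queries = nrow(lib$queries),
        library_hash = rlang::hash(lapply(lib$templates, function(s) {
          list(s$chain_id, s$topology, paste(s$residues$aa, collapse = ""))
        })),
        jackknife_k = jackknife_k,
        accuracy = accuracy
      ),
      file.path(out_dir, "provenance.json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  out
}

#' Predict the fold class of one query
#'
#' The prediction pipeline: topology-filter the template library against
#' the query grammar (optionally also the short-linker filter), thread
#' the query onto every accepted template, rank by energy and attach
#' reliability scores.
#'
#' @param query a [tmf_query()].
#' @param templates named list of `tmf_structure`.
#' @param potential a `tmf_potential`.
#' @param zdist optional `tmf_zdist` (required for templates with
#'   unknown-identity neighbors).
#' @param reliability a [reliability_model()].
#' @param topology_filter apply the grammar filter (default TRUE; when
#'   off, only the equal-segment-count requirement remains).
#' @param linker_filter also apply [linker_length_filter()] (default
#'   FALSE).
#' @param ts_threshold topology similarity threshold (default 0.9).
#' @param out_file optional TSV path for the ranking.
#' @return List with `ranking` (a `tmf_ranking`), `screen` (per-template
#'   filter table), `status` (`"ok"` or `"no_compatible_fold"`).
#' @export
run_predict <- function(query, templates, potential, zdist = NULL,
                        reliability = default_reliability_model(),
                        topology_filter = TRUE, linker_filter = FALSE,
                        ts_threshold = 0.9, out_file = NULL) {
  topos <- lapply(templates, function(s) s$topology)
  scr <- topology_screen(query$grammar, topos, ts_threshold)
  if (!topology_filter) {
    scr$accepted <- scr$ntm_match
  }
  if (linker_filter) {
    keep <- vapply(seq_along(templates), function(i) {
      linker_length_filter(query$topology, templates[[i]]$topology)
    }, logical(1))
    scr$accepted <- scr$accepted & keep
  }
  kept <- templates[scr$accepted]
  ranking <- rank_library(query, kept, potential, zdist, reliability)
  if (!is.null(out_file) && nrow(ranking) > 0L) {
    utils::write.table(as.data.frame(ranking), out_file, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  list(
    ranking = ranking,
    screen = scr,
    status = if (nrow(ranking) == 0L) "no_compatible_fold" else "ok"
  )
}

#' Score every query of a library against its templates
#'
#' Convenience benchmark: runs [run_predict()] for each query of a
#' library with a fixed potential, and reports per-query correctness and
#' the random baseline `1/F` over compatible fold classes.
#'
#' @inheritParams run_predict
#' @param lib a `tmf_library`.
#' @return Tibble with one row per query: `query_id`,
#'   `native_template`, `predicted`, `correct`, `reduced_energy`,
#'   `reliability`, `random_baseline`.
#' @export
benchmark_library <- function(lib, potential, zdist = NULL,
                              reliability = default_reliability_model(),
                              topology_filter = TRUE) {
  rows <- list()
  for (i in seq_len(nrow(lib$queries))) {
    q <- lib$queries[i, ]
    res <- run_predict(tmf_query(q$sequence, q$topology), lib$templates,
                       potential, zdist, reliability,
                       topology_filter = topology_filter)
    rk <- res$ranking
    rows[[i]] <- tibble(
      query_id = q$query_id,
      native_template = q$native_template,
      predicted = if (nrow(rk) > 0) rk$template_id[1] else NA_character_,
      correct = if (nrow(rk) > 0) rk$template_id[1] == q$native_template else FALSE,
      reduced_energy = if (nrow(rk) > 0) rk$reduced_energy[1] else NA_real_,
      reliability = if (nrow(rk) > 0) rk$reliability[1] else NA_real_,
      random_baseline = if (nrow(rk) > 0) random_baseline(nrow(rk)) else NA_real_
    )
  }
  bind_rows(rows)
}
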