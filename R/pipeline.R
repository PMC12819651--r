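# Orchestration: configuration, the simulate/mine/naping commands and their
# machine-readable run summaries. inst/cli/herbfront.R wraps these for shell
# use.

default_config <- function() {
  list(
    out_dir = ".",
    corpus = NULL, terms = NULL, annotation = NULL,
    plates = list(),
    min_count = 10, max_rank = 3,
    alpha_tiers = c(0.05, 0.01, 0.001),
    lfc_threshold = 1, min_len = 3, tolerance = 1,
    partial_band = c(0.5, 1),
    seed = 1,
    simulate = list()
  )
}

#' Build and validate a run configuration
#'
#' Configuration can come from a YAML file, a list, or both; `...` overrides
#' take precedence over the file, which takes precedence over the defaults.
#' All randomness in the commands flows from the single `seed` field.
#'
#' @param path Optional YAML file.
#' @param ... Named overrides of individual fields.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(paste0("config file not found: ", path))
    file_cfg <- yaml::read_yaml(path)
    cfg[names(file_cfg)] <- file_cfg
  }
  overrides <- list(...)
  cfg[names(overrides)] <- overrides

  cfg$alpha_tiers <- as.numeric(cfg$alpha_tiers)
  if (length(cfg$alpha_tiers) != 3 || any(diff(cfg$alpha_tiers) >= 0)) {
    abort("alpha_tiers must be three strictly decreasing levels")
  }
  for (f in c("min_count", "max_rank", "lfc_threshold", "min_len")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      abort(paste0("config field '", f, "' must be positive"))
    }
  }
  if (cfg$tolerance < 0) abort("tolerance must be non-negative")
  cfg$partial_band <- as.numeric(cfg$partial_band)
  if (length(cfg$partial_band) != 2 ||
      cfg$partial_band[1] <= 0 || cfg$partial_band[1] >= cfg$partial_band[2]) {
    abort("partial_band must be an increasing pair of proportions")
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

write_summary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate input files for a run
#'
#' Generates a synthetic corpus (with its search-term table) and/or binding
#' plates according to the `simulate` section of the configuration and
#' writes them, plus JSON truth sidecars, into `out_dir`. The `simulate`
#' section may carry a `corpus` sublist (arguments to [corpus_spec()]) and a
#' `plates` sublist (a list of argument lists to [plate_spec()]); an empty
#' section simulates a default corpus.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of the files written.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!dir.exists(out)) {
    ok <- dir.create(out, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", out))
  }
  message("simulate: seed = ", config$seed)
  files <- list()
  sim <- config$simulate %||% list()

  cargs <- sim$corpus %||% list()
  if (!identical(cargs, FALSE)) {
    cargs$seed <- cargs$seed %||% config$seed
    spec <- do.call(corpus_spec, cargs)
    gen <- generate_corpus(spec)
    files$corpus <- file.path(out, "corpus.csv")
    files$terms <- file.path(out, "search_terms.csv")
    files$corpus_truth <- file.path(out, "corpus_truth.json")
    write_corpus(gen$corpus, files$corpus)
    readr::write_csv(as_tibble(gen$terms), files$terms)
    truth <- gen$truth
    truth$planted$target <- lapply(truth$planted$target, as.list)
    jsonlite::write_json(truth, files$corpus_truth, auto_unbox = TRUE,
                         dataframe = "rows", digits = NA)
  }
  pargs_list <- sim$plates %||% list()
  for (i in seq_along(pargs_list)) {
    pargs <- pargs_list[[i]]
    pargs$seed <- pargs$seed %||% (config$seed + i)
    spec <- do.call(plate_spec, pargs)
    gen <- generate_plate(spec)
    stem <- file.path(out, paste0("plate_", spec$plant_id))
    files[[paste0("plate_", i)]] <- paste0(stem, ".csv")
    files[[paste0("plate_truth_", i)]] <- paste0(stem, "_truth.json")
    write_plate(gen$plate, paste0(stem, ".csv"))
    tr <- gen$truth
    tr$true_lfc <- NULL  # large matrix; boundaries and motifs suffice
    tr$clusters$motifs <- lapply(tr$clusters$motifs, as.list)
    jsonlite::write_json(tr, paste0(stem, "_truth.json"), auto_unbox = TRUE,
                         dataframe = "rows", digits = NA)
  }
  invisible(files)
}

#' Run the corpus-mining stage
#'
#' Links recipes to search terms, builds the joint dataset and its four
#' subsets, computes frequencies, applies the occurrence threshold on the
#' joint dataset, assigns Pareto-front ranks (subsets inherit the
#' joint-filtered drug list), and writes per-dataset ranked-point CSVs, the
#' cross-subset rank matrix and a machine-readable JSON run summary.
#'
#' @param config A [run_config()] with `corpus` and `terms` paths set.
#' @return Invisibly, a list with `results` (named `pareto_result`s),
#'   `matrix` (the [rank_matrix()]) and `summary`.
#' @export
cmd_mine <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$corpus) || is.null(config$terms)) {
    abort("config must set 'corpus' and 'terms' paths")
  }
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  co <- read_corpus(config$corpus)
  terms <- read_search_terms(config$terms)
  annotation <- if (!is.null(config$annotation)) {
    read_annotation(config$annotation)
  } else NULL

  subsets <- build_subsets(co, terms)
  freqs <- compute_frequencies(co, subsets$all_terms)
  thr <- apply_threshold(freqs, co, subsets$all_terms,
                         min_count = config$min_count)
  joint <- pareto_ranks(thr$points, max_rank = config$max_rank,
                        dataset_name = "all_terms")

  results <- list(all_terms = joint)
  for (nm in setdiff(names(subsets), "all_terms")) {
    sel <- subsets[[nm]]
    if (length(sel$recipe_ids) == 0) next
    f <- compute_frequencies(co, sel)
    f <- f[f$drug %in% thr$points$drug, ]
    if (nrow(f) == 0) next
    results[[nm]] <- pareto_ranks(f, max_rank = config$max_rank,
                                  dataset_name = nm)
  }
  rm_tab <- rank_matrix(joint, results[setdiff(names(results), "all_terms")],
                        annotation = annotation)

  for (nm in names(results)) {
    write_pareto_csv(results[[nm]], file.path(out, paste0("ranks_", nm, ".csv")))
  }
  write_pareto_csv(rm_tab, file.path(out, "rank_matrix.csv"))

  sizes <- subset_sizes(subsets)
  attribution <- subsets$arthritis_main_orbit$attribution
  summary <- list(
    seed = config$seed,
    min_count = config$min_count,
    max_rank = config$max_rank,
    dataset_sizes = stats::setNames(as.list(sizes$n_recipes), sizes$subset),
    arthritis_main = sum(attribution$group == "Main"),
    arthritis_orbit = sum(attribution$group == "Orbit"),
    dropped = list(drugs = length(thr$dropped_drugs),
                   recipes = length(thr$dropped_recipes),
                   terms = length(thr$dropped_terms)),
    retained = list(drugs = nrow(thr$points),
                    recipes = length(thr$selection$recipe_ids),
                    terms = nrow(thr$selection$terms_used)),
    rank_counts = as.list(table(joint$points$rank)),
    candidates = rm_tab$drug
  )
  write_summary(summary, file.path(out, "mine_summary.json"))
  invisible(list(results = results, matrix = rm_tab, summary = summary))
}

#' Run the binding-plate analysis stage
#'
#' For each entry of `config$plates` — a list with `screening` (path),
#' optional `confirmation` (path) and optional `spiked_motif` — this runs
#' modulation, motif classification and active-cluster detection on the
#' screening plate; confirms each cluster apex on the confirmation plate
#' when given; and, when a spiked condition is present there, derives the
#' competitive-inhibition call. Writes a clusters CSV, a calls CSV shaped
#' like the standard overview table (Plant, Fraction position, Activity,
#' Motif, Inhibition) and a JSON run summary.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `clusters`, `calls` and `summary`.
#' @export
cmd_naping <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (length(config$plates) == 0) abort("config lists no plates")
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  alpha <- config$alpha_tiers[1]

  all_clusters <- list()
  calls <- list()
  for (entry in config$plates) {
    plate <- read_plate(entry$screening)
    cl <- detect_clusters(plate, min_len = config$min_len,
                          lfc_threshold = config$lfc_threshold,
                          tolerance = config$tolerance)
    if (nrow(cl) == 0) next
    conf_plate <- if (!is.null(entry$confirmation)) {
      read_plate(entry$confirmation)
    } else NULL
    for (i in seq_len(nrow(cl))) {
      row <- cl[i, ]
      confirmed <- NA
      inhib <- NA_character_
      spiked <- NA_character_
      if (!is.null(conf_plate)) {
        conf <- confirm_apex(conf_plate, row, alpha = alpha)
        confirmed <- is_confirmed(conf)
        if (!is.null(entry$spiked_motif)) {
          spike_cond <- paste0(row$apex_well, "+", entry$spiked_motif)
          if (spike_cond %in% conf_plate$conditions$condition) {
            ic <- inhibition_call(conf_plate, stimulus = row$apex_well,
                                  spiked_motif = entry$spiked_motif,
                                  alpha = alpha,
                                  partial_band = config$partial_band)
            inhib <- ic$call
            spiked <- entry$spiked_motif
          }
        }
      }
      span <- if (row$start == row$end) row$start_well else
        paste0(row$start_well, "-", row$end_well)
      calls[[length(calls) + 1L]] <- tibble(
        plant = row$plant_id,
        fraction_position = span,
        apex = row$apex_well,
        activity = ifelse(is.na(confirmed), NA_character_,
                          ifelse(confirmed, "+", "-")),
        motif = spiked,
        inhibition = inhib
      )
    }
    all_clusters[[length(all_clusters) + 1L]] <- cl
  }

  clusters_tab <- if (length(all_clusters)) bind_rows(all_clusters) else NULL
  calls_tab <- if (length(calls)) bind_rows(calls) else
    tibble(plant = character(0), fraction_position = character(0),
           apex = character(0), activity = character(0),
           motif = character(0), inhibition = character(0))

  flat <- if (is.null(clusters_tab)) tibble() else as_tibble(clusters_tab)
  if (nrow(flat) > 0) {
    flat$motifs <- vapply(flat$motifs, paste, "", collapse = "|")
    flat <- flat[, c("plant_id", "cluster_id", "start_well", "apex_well",
                     "end_well", "start", "apex", "end", "n_fractions",
                     "peak_lfc", "motifs")]
  } else {
    flat <- tibble(plant_id = character(0), cluster_id = integer(0),
                   start_well = character(0), apex_well = character(0),
                   end_well = character(0), start = integer(0),
                   apex = integer(0), end = integer(0),
                   n_fractions = integer(0), peak_lfc = numeric(0),
                   motifs = character(0))
  }
  readr::write_csv(flat, file.path(out, "clusters.csv"))
  readr::write_csv(calls_tab, file.path(out, "calls.csv"))

  summary <- list(
    seed = config$seed,
    n_plates = length(config$plates),
    n_clusters = nrow(flat),
    n_cluster_fractions = sum(flat$n_fractions),
    n_confirmed = sum(calls_tab$activity == "+", na.rm = TRUE),
    calls = as.list(stats::setNames(calls_tab$inhibition,
                                    paste(calls_tab$plant,
                                          calls_tab$fraction_position)))
  )
  write_summary(summary, file.path(out, "naping_summary.json"))
  invisible(list(clusters = flat, calls = calls_tab, summary = summary))
}
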