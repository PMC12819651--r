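# Seeded generators for recipe corpora and binding plates with planted,
# fully recorded ("truth") structure, so every analysis stage can be tested
# against known ground truth.

#' Default synthetic search-term table
#'
#' 74 search terms mirroring the structure of the historical term list:
#' 16 main-granularity arthritis terms, 24 orbit-granularity arthritis terms
#' and 34 skin terms. Term strings are synthetic identifiers.
#'
#' @return A [search_terms()] tibble.
#' @export
default_search_terms <- function() {
  search_terms(tibble(
    term = c(sprintf("arth main %02d", 1:16),
             sprintf("arth orbit %02d", 1:24),
             sprintf("skin term %02d", 1:34)),
    transliteration = "",
    category = rep(c("arthritis", "arthritis", "skin"), c(16, 24, 34)),
    granularity = rep(c("main", "orbit", "none"), c(16, 24, 34))
  ))
}

#' Specification for a synthetic recipe corpus
#'
#' The generator emulates the statistical structure of a large historical
#' recipe corpus, scaled down: a heavy-headed (power-law) background
#' ingredient distribution, indication terms organised in disease domains of
#' which two (arthritis and skin) contain the search terms, and planted
#' drugs with known frequency/specificity structure. Defaults scale the
#' emulated corpus (41,359 recipes / 2,893 indications / 3,638 ingredients)
#' by roughly 1/8 on recipes and ingredients and 1/5 on terms, keeping both
#' the ~25% share of musculoskeletal/skin recipes and the ~5% share of
#' search-term-linked recipes.
#'
#' Planted *specific* drugs appear at `in_rate` in recipes linked to their
#' target term set and at `out_rate` elsewhere (high relative frequency,
#' modest frequency); planted *common* drugs appear corpus-wide at `rate`,
#' with a `common_boost` multiplier inside search-term-linked recipes (the
#' mild indication enrichment that ubiquitous drugs show in practice).
#'
#' @param n_recipes Number of recipes (default 5000).
#' @param n_ingredients Background ingredient vocabulary size (default 450).
#' @param n_generalists Number of popular drugs usable in every domain
#'   (default 60); the remaining drugs are specialists with 1-3 home domains.
#' @param zipf_exponent Power-law exponent of background drug popularity
#'   (default 0.8).
#' @param mean_ingredients Mean ingredients per recipe, as `1 + Poisson`
#'   (default 7).
#' @param n_other_domains Background disease domains besides arthritis and
#'   skin (default 8).
#' @param terms_arthritis,terms_skin,terms_per_other_domain Term counts per
#'   domain (defaults 180, 160, 30); the 74 search terms of
#'   [default_search_terms()] are embedded in the arthritis and skin domains.
#' @param domain_weight_arthritis,domain_weight_skin Recipe shares of the two
#'   focal domains (defaults 0.13 and 0.12).
#' @param term_zipf_exponent Power-law exponent of term popularity within a
#'   domain (default 1.0).
#' @param cross_domain_rate Probability that a recipe carries an extra term
#'   from a second domain (default 0.10); this is what creates
#'   arthritis-and-skin intersections.
#' @param planted_specific Tibble `drug`, `target` (list of term vectors),
#'   `in_rate`, `out_rate`. Default: three drugs targeting all arthritis
#'   terms, the skin terms and the main arthritis terms at in-set rates
#'   0.30/0.30/0.45 and out-of-set rate 0.001.
#' @param planted_common Tibble `drug`, `rate`. Default: three drugs at
#'   global rates 0.16/0.12/0.08.
#' @param common_boost In-selection presence multiplier for planted common
#'   drugs (default 2).
#' @param seed Integer seed; every stochastic draw flows from it.
#' @return Object of class `corpus_spec` (a list of the above).
#' @export
corpus_spec <- function(n_recipes = 5000,
                        n_ingredients = 450,
                        n_generalists = 60,
                        zipf_exponent = 0.8,
                        mean_ingredients = 7,
                        n_other_domains = 8,
                        terms_arthritis = 180,
                        terms_skin = 160,
                        terms_per_other_domain = 30,
                        domain_weight_arthritis = 0.13,
                        domain_weight_skin = 0.12,
                        term_zipf_exponent = 1.0,
                        cross_domain_rate = 0.10,
                        planted_specific = NULL,
                        planted_common = NULL,
                        common_boost = 2,
                        seed = 1) {
  terms <- default_search_terms()
  if (is.null(planted_specific)) {
    planted_specific <- tibble(
      drug = sprintf("planted specific %d", 1:3),
      target = list(terms$term[terms$category == "arthritis"],
                    terms$term[terms$category == "skin"],
                    terms$term[terms$granularity == "main"]),
      in_rate = c(0.30, 0.30, 0.45),
      out_rate = c(0.001, 0.001, 0.001)
    )
  }
  if (is.null(planted_common)) {
    planted_common <- tibble(
      drug = sprintf("planted common %d", 1:3),
      rate = c(0.16, 0.12, 0.08)
    )
  }
  rates <- c(planted_specific$in_rate, planted_specific$out_rate,
             planted_common$rate)
  if (any(rates < 0 | rates > 1)) abort("planted rates must lie in [0, 1]")
  if (anyDuplicated(c(planted_specific$drug, planted_common$drug))) {
    abort("planted drugs must be disjoint")
  }
  structure(
    list(n_recipes = n_recipes, n_ingredients = n_ingredients,
         n_generalists = n_generalists, zipf_exponent = zipf_exponent,
         mean_ingredients = mean_ingredients,
         n_other_domains = n_other_domains,
         terms_arthritis = terms_arthritis, terms_skin = terms_skin,
         terms_per_other_domain = terms_per_other_domain,
         domain_weight_arthritis = domain_weight_arthritis,
         domain_weight_skin = domain_weight_skin,
         term_zipf_exponent = term_zipf_exponent,
         cross_domain_rate = cross_domain_rate,
         planted_specific = as_tibble(planted_specific),
         planted_common = as_tibble(planted_common),
         common_boost = common_boost,
         search_terms = terms,
         seed = as.integer(seed)),
    class = "corpus_spec"
  )
}

#' Generate a synthetic recipe corpus with planted structure
#'
#' See [corpus_spec()] for the generative model. The returned truth record
#' documents every planted assignment so that downstream recovery can be
#' checked against it.
#'
#' @param spec A [corpus_spec()].
#' @return List with `corpus` (a [corpus()]), `terms` (the search-term
#'   table) and `truth` (list: `planted` tibble with realized in/out counts,
#'   `selection_ids`, per-recipe `domains`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  withr::with_seed(spec$seed, generate_corpus_impl(spec))
}

generate_corpus_impl <- function(spec) {
  n <- spec$n_recipes
  st <- spec$search_terms

  # --- term universe: domains hold Zipf-weighted terms; the search terms
  # are embedded at random popularity ranks of their domain
  n_dom <- spec$n_other_domains + 2L
  dom_names <- c("arthritis", "skin", sprintf("domain%02d", seq_len(spec$n_other_domains)))
  dom_sizes <- c(spec$terms_arthritis, spec$terms_skin,
                 rep(spec$terms_per_other_domain, spec$n_other_domains))
  arth_terms <- st$term[st$category == "arthritis"]
  skin_terms <- st$term[st$category == "skin"]
  if (dom_sizes[1] < length(arth_terms) || dom_sizes[2] < length(skin_terms)) {
    abort("focal domains too small to hold the search terms")
  }
  dom_terms <- vector("list", n_dom)
  dom_terms[[1]] <- sample(c(arth_terms,
                             sprintf("arth bg %03d",
                                     seq_len(dom_sizes[1] - length(arth_terms)))))
  dom_terms[[2]] <- sample(c(skin_terms,
                             sprintf("skin bg %03d",
                                     seq_len(dom_sizes[2] - length(skin_terms)))))
  for (d in 3:n_dom) {
    dom_terms[[d]] <- sprintf("%s term %03d", dom_names[d], seq_len(dom_sizes[d]))
  }
  term_w <- lapply(dom_sizes, function(k) {
    w <- seq_len(k)^(-spec$term_zipf_exponent)
    w / sum(w)
  })

  # --- per-recipe indications
  w_other <- (1 - spec$domain_weight_arthritis - spec$domain_weight_skin) /
    spec$n_other_domains
  dom_w <- c(spec$domain_weight_arthritis, spec$domain_weight_skin,
             rep(w_other, spec$n_other_domains))
  primary <- sample.int(n_dom, n, replace = TRUE, prob = dom_w)
  n_terms_recipe <- 1L + stats::rbinom(n, 2, 0.2)
  cross <- stats::runif(n) < spec$cross_domain_rate
  cross_dom <- sample.int(n_dom, n, replace = TRUE, prob = dom_w)
  indications <- lapply(seq_len(n), function(i) {
    d <- primary[i]
    ind <- sample(dom_terms[[d]], min(n_terms_recipe[i], dom_sizes[d]),
                  prob = term_w[[d]])
    if (cross[i] && cross_dom[i] != d) {
      d2 <- cross_dom[i]
      ind <- c(ind, sample(dom_terms[[d2]], 1, prob = term_w[[d2]]))
    }
    unique(ind)
  })

  # --- background ingredients: Zipf popularity; top drugs are generalists,
  # the tail are specialists with 1-3 home domains
  k <- spec$n_ingredients
  drug_names <- sprintf("drug %03d", seq_len(k))
  w <- seq_len(k)^(-spec$zipf_exponent)
  generalist <- seq_len(k) <= spec$n_generalists
  n_home <- 1L + stats::rbinom(k, 2, 0.2)
  homes <- lapply(seq_len(k), function(j) {
    if (generalist[j]) seq_len(n_dom) else sample.int(n_dom, n_home[j])
  })
  # eligibility list per domain
  eligible <- lapply(seq_len(n_dom), function(d) {
    which(vapply(homes, function(h) d %in% h, logical(1)))
  })
  size <- pmin(1L + stats::rpois(n, spec$mean_ingredients - 1),
               vapply(eligible[primary], length, integer(1)))
  ingredients <- lapply(seq_len(n), function(i) {
    el <- eligible[[primary[i]]]
    drug_names[el[sample.int(length(el), size[i], prob = w[el])]]
  })

  # --- planted drugs
  in_selection <- vapply(indications, function(ind) any(ind %in% st$term),
                         logical(1))
  ps <- spec$planted_specific
  planted_rows <- list()
  for (j in seq_len(nrow(ps))) {
    tgt <- ps$target[[j]]
    hit <- vapply(indications, function(ind) any(ind %in% tgt), logical(1))
    if (ps$in_rate[j] * sum(hit) < 1) {
      abort(paste0("infeasible planted rate: expected in-set count < 1 for ",
                   ps$drug[j]))
    }
    p <- ifelse(hit, ps$in_rate[j], ps$out_rate[j])
    present <- stats::runif(n) < p
    ingredients[present] <- lapply(ingredients[present], c, ps$drug[j])
    planted_rows[[length(planted_rows) + 1L]] <- tibble(
      drug = ps$drug[j], role = "specific",
      target = list(tgt), in_rate = ps$in_rate[j], out_rate = ps$out_rate[j],
      n_target_recipes = sum(hit),
      n_in = sum(present & hit), n_out = sum(present & !hit),
      db_total = sum(present)
    )
  }
  pc <- spec$planted_common
  for (j in seq_len(nrow(pc))) {
    p <- pmin(1, pc$rate[j] * ifelse(in_selection, spec$common_boost, 1))
    if (pc$rate[j] * n < 1) {
      abort(paste0("infeasible planted rate: expected count < 1 for ",
                   pc$drug[j]))
    }
    present <- stats::runif(n) < p
    ingredients[present] <- lapply(ingredients[present], c, pc$drug[j])
    planted_rows[[length(planted_rows) + 1L]] <- tibble(
      drug = pc$drug[j], role = "common",
      target = list(character(0)), in_rate = NA_real_, out_rate = pc$rate[j],
      n_target_recipes = NA_integer_,
      n_in = sum(present & in_selection), n_out = sum(present & !in_selection),
      db_total = sum(present)
    )
  }

  recipes <- tibble(
    recipe_id = sprintf("R%05d", seq_len(n)),
    title = sprintf("recipe %d", seq_len(n)),
    source_id = sprintf("MS%03d", sample.int(227, n, replace = TRUE)),
    indications = indications,
    ingredients = ingredients
  )
  co <- corpus(recipes)
  list(
    corpus = co,
    terms = st,
    truth = list(
      planted = bind_rows(planted_rows),
      selection_ids = recipes$recipe_id[in_selection],
      domains = dom_names[primary]
    )
  )
}

# ---- binding plates -----------------------------------------------------

#' Default motif library
#'
#' 101 motif identifiers: the five named coregulator motifs used throughout
#' (NCOA1, PELP1, DHX30, NCOR2, IKBB) plus generic identifiers.
#'
#' @return Character vector of length 101.
#' @export
default_motifs <- function() {
  c("NCOA1", "PELP1", "DHX30", "NCOR2", "IKBB",
    sprintf("MOTIF%03d", 6:101))
}

#' Specification for a synthetic binding plate
#'
#' Emulates a coregulator-binding assay plate: per-motif log-normal Apo
#' baselines, fold-change effects of the cortisol control on designated
#' GC-responsive motifs (the NCOA1-like motif is induced >1000-fold by
#' default), Gaussian LFC bumps over the sequential fraction axis for planted
#' active clusters, and log-normal multiplicative replicate noise
#' (coefficient of variation `cv`, default 10%). A motif listed both under
#' `gc_folds` and in a cluster (IKBB by default) is a *shared* motif. An
#' optional spike scenario adds a competition condition
#' `<stimulus>+<motif>`.
#'
#' @param plant_id Plate identifier.
#' @param motifs Motif identifiers (default [default_motifs()], n = 101).
#' @param n_fractions Number of sequential fractions (default 96).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-motif Apo baseline (defaults `log(500)`, 0.8).
#' @param cv Replicate coefficient of variation (default 0.10).
#' @param gc_folds Named numeric vector of cortisol fold changes
#'   (default: NCOA1 = 1200, IKBB = 6 and six generic motifs at folds 2-20).
#' @param clusters List of planted clusters, each
#'   `list(motifs=, center=, width=, peak_lfc=, direction=1)`: a Gaussian
#'   LFC profile `peak_lfc * exp(-(i - center)^2 / (2 width^2))` on each
#'   listed motif. Default: one cluster on PELP1/DHX30/NCOR2/IKBB centred at
#'   fraction 28 (well C4), width 3, peak LFC 2.5.
#' @param control_reps Replicates of Apo and Cortisol (default 3).
#' @param fraction_reps Replicates per fraction: 1 for screening plates,
#'   3 for confirmation plates.
#' @param fractions Fraction indices present on the plate (default all).
#' @param spike Optional `list(stimulus=, motif=, scenario=)` with scenario
#'   in `full`, `none`, `partial`; `partial_prop` (default 0.6) sets the
#'   proportion of responsive motifs inhibited under `partial`.
#' @param allow_merge Allow overlapping planted clusters on a shared motif
#'   (default FALSE: overlapping same-motif clusters are an error).
#' @param truth_lfc Absolute true-LFC level defining the recorded footprint
#'   of a planted cluster (default 1).
#' @param seed Integer seed.
#' @return Object of class `plate_spec`.
#' @export
plate_spec <- function(plant_id = "plant",
                       motifs = default_motifs(),
                       n_fractions = 96,
                       baseline_meanlog = log(500),
                       baseline_sdlog = 0.8,
                       cv = 0.10,
                       gc_folds = c(NCOA1 = 1200, IKBB = 6, MOTIF006 = 20,
                                    MOTIF007 = 8, MOTIF008 = 5, MOTIF009 = 3,
                                    MOTIF010 = 2.5, MOTIF011 = 2),
                       clusters = list(list(
                         motifs = c("PELP1", "DHX30", "NCOR2", "IKBB"),
                         center = 28, width = 3, peak_lfc = 2.5,
                         direction = 1)),
                       control_reps = 3,
                       fraction_reps = 1,
                       fractions = seq_len(n_fractions),
                       spike = NULL,
                       allow_merge = FALSE,
                       truth_lfc = 1,
                       seed = 1) {
  if (is.null(gc_folds)) gc_folds <- numeric(0)
  if (is.null(clusters)) clusters <- list()
  if (length(gc_folds) > 0 && !all(names(gc_folds) %in% motifs)) {
    abort("gc_folds names unknown motifs")
  }
  spans <- list()
  for (cl in clusters) {
    stopifnot(all(cl$motifs %in% motifs), cl$peak_lfc > 0, cl$width > 0)
    if (cl$center < 1 || cl$center > n_fractions) {
      abort("cluster center outside 1..n_fractions")
    }
    half <- if (cl$peak_lfc <= truth_lfc) 0 else
      cl$width * sqrt(2 * log(cl$peak_lfc / truth_lfc))
    span <- c(max(1, ceiling(cl$center - half)),
              min(n_fractions, floor(cl$center + half)))
    for (m in cl$motifs) {
      prev <- spans[[m]]
      if (!is.null(prev) && !allow_merge &&
          any(vapply(prev, function(s) span[1] <= s[2] && s[1] <= span[2],
                     logical(1)))) {
        abort(paste0("overlapping planted clusters on motif ", m,
                     " (set allow_merge = TRUE to permit)"))
      }
      spans[[m]] <- c(prev, list(span))
    }
  }
  if (!is.null(spike)) {
    stopifnot(is.list(spike), !is.null(spike$stimulus), !is.null(spike$motif),
              spike$scenario %in% c("full", "none", "partial"))
    if (is.null(spike$partial_prop)) spike$partial_prop <- 0.6
  }
  structure(
    list(plant_id = plant_id, motifs = motifs, n_fractions = n_fractions,
         baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
         cv = cv, gc_folds = gc_folds, clusters = clusters,
         control_reps = control_reps, fraction_reps = fraction_reps,
         fractions = fractions, spike = spike, truth_lfc = truth_lfc,
         seed = as.integer(seed)),
    class = "plate_spec"
  )
}

# True (noise-free) LFC of motif m at fraction i, summed over clusters.
cluster_lfc_matrix <- function(spec) {
  m <- matrix(0, nrow = length(spec$motifs), ncol = spec$n_fractions,
              dimnames = list(spec$motifs, NULL))
  for (cl in spec$clusters) {
    dir <- cl$direction %||% 1
    prof <- cl$peak_lfc * exp(-((seq_len(spec$n_fractions) - cl$center)^2) /
                                (2 * cl$width^2)) * dir
    m[cl$motifs, ] <- m[cl$motifs, , drop = FALSE] +
      matrix(prof, nrow = length(cl$motifs), ncol = spec$n_fractions,
             byrow = TRUE)
  }
  m
}

#' Generate a synthetic binding plate with planted effects
#'
#' See [plate_spec()] for the generative model. The truth record carries the
#' planted cluster boundaries (fractions where the true `|LFC|` reaches
#' `truth_lfc`), the responsive motif sets, the GC folds and the intended
#' inhibition call, for use as an oracle in recovery tests.
#'
#' @param spec A [plate_spec()].
#' @return List with `plate` (a [binding_plate()]) and `truth` (list:
#'   `clusters` tibble with `start`/`apex`/`end`/`motifs`, `gc_folds`,
#'   `true_lfc` matrix, `responsive`, `intended_call`).
#' @export
generate_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  withr::with_seed(spec$seed, generate_plate_impl(spec))
}

generate_plate_impl <- function(spec) {
  motifs <- spec$motifs
  nm <- length(motifs)
  sdlog <- sqrt(log(1 + spec$cv^2))
  baseline <- stats::rlnorm(nm, spec$baseline_meanlog, spec$baseline_sdlog)
  names(baseline) <- motifs

  cort_mu <- baseline
  if (length(spec$gc_folds) > 0) {
    cort_mu[names(spec$gc_folds)] <-
      baseline[names(spec$gc_folds)] * spec$gc_folds
  }
  lfc_true <- cluster_lfc_matrix(spec)

  draw <- function(mu, condition, reps) {
    n <- length(mu) * reps
    tibble(
      motif = rep(motifs, times = reps),
      condition = condition,
      replicate = rep(seq_len(reps), each = length(mu)),
      value = rep(mu, times = reps) * exp(stats::rnorm(n, 0, sdlog))
    )
  }

  parts <- list(
    draw(baseline, "Apo", spec$control_reps),
    draw(cort_mu, "Cortisol", spec$control_reps)
  )
  for (i in spec$fractions) {
    mu_i <- baseline * 2^lfc_true[, i]
    parts[[length(parts) + 1L]] <- draw(mu_i, index_well(i),
                                        spec$fraction_reps)
  }

  responsive <- character(0)
  intended_call <- NULL
  if (!is.null(spec$spike)) {
    sp <- spec$spike
    if (is_well_label(sp$stimulus)) {
      i <- well_index(sp$stimulus)
      stim_mu <- baseline * 2^lfc_true[, i]
      responsive <- motifs[lfc_true[, i] >= spec$truth_lfc]
    } else {
      stim_mu <- cort_mu
      responsive <- names(spec$gc_folds)[spec$gc_folds > 1]
    }
    inhibited <- switch(sp$scenario,
      full = responsive,
      none = character(0),
      partial = responsive[seq_len(ceiling(sp$partial_prop *
                                             length(responsive)))]
    )
    spike_mu <- stim_mu
    spike_mu[inhibited] <- baseline[inhibited]
    parts[[length(parts) + 1L]] <-
      draw(spike_mu, paste0(sp$stimulus, "+", sp$motif), spec$control_reps)
    intended_call <- switch(sp$scenario, full = "+", none = "-",
                            partial = "±")
  }

  plate <- binding_plate(bind_rows(parts), plant_id = spec$plant_id)

  truth_clusters <- purrr::map_dfr(seq_along(spec$clusters), function(j) {
    cl <- spec$clusters[[j]]
    prof <- abs(cl$peak_lfc) * exp(-((seq_len(spec$n_fractions) -
                                        cl$center)^2) / (2 * cl$width^2))
    foot <- which(prof >= spec$truth_lfc)
    tibble(cluster_id = j,
           start = if (length(foot)) min(foot) else NA_integer_,
           apex = round(cl$center),
           end = if (length(foot)) max(foot) else NA_integer_,
           n_fractions = length(foot),
           peak_lfc = cl$peak_lfc, motifs = list(cl$motifs))
  })
  list(
    plate = plate,
    truth = list(clusters = truth_clusters,
                 gc_folds = spec$gc_folds,
                 true_lfc = lfc_true,
                 responsive = responsive,
                 intended_call = intended_call)
  )
}
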