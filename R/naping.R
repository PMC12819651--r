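# Modulation statistics, motif classification, active-cluster detection,
# apex confirmation and competitive-inhibition calls.

star_tiers <- function(p, tiers = c(0.05, 0.01, 0.001)) {
  stopifnot(length(tiers) == 3, all(diff(tiers) < 0))
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < tiers[3] ~ "***",
    p < tiers[2] ~ "**",
    p < tiers[1] ~ "*",
    TRUE ~ "ns"
  )
}

welch_p <- function(x, y, alternative = "two.sided") {
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  tryCatch(stats::t.test(x, y, alternative = alternative)$p.value,
           error = function(e) NA_real_)
}

#' Per-motif modulation of receptor binding relative to Apo
#'
#' For each motif and requested condition, the log2 fold change of the
#' condition mean over the Apo mean is computed with a pseudo-count
#' (`lfc = log2(mean(cond) + eps) - log2(mean(Apo) + eps)`), and — when both
#' groups carry at least two technical replicates — a two-sided Welch
#' two-sample t-test against the Apo replicates. Significance tiers follow
#' the conventional star scheme (`*` p < 0.05, `**` p < 0.01, `***`
#' p < 0.001). Single-replicate (screening) conditions get an LFC only; no
#' p-value is invented for them.
#'
#' @param plate A [binding_plate()].
#' @param condition Character vector of condition names; defaults to every
#'   non-Apo condition on the plate.
#' @param eps Pseudo-count in fluorescence units guarding zero signals
#'   (default 1).
#' @param tiers Decreasing significance thresholds (default 0.05, 0.01,
#'   0.001).
#' @param alternative Test sidedness passed to the Welch test.
#' @return Tibble: `motif`, `condition`, `lfc`, `p_value`, `stars`,
#'   `n_condition`, `n_apo`.
#' @export
modulation <- function(plate, condition = NULL, eps = 1,
                       tiers = c(0.05, 0.01, 0.001),
                       alternative = "two.sided") {
  stopifnot(inherits(plate, "binding_plate"))
  apo_name <- plate$conditions$condition[plate$conditions$type == "apo"]
  if (is.null(condition)) {
    condition <- setdiff(plate$conditions$condition, apo_name)
  }
  unknown <- setdiff(condition, plate$conditions$condition)
  if (length(unknown) > 0) {
    abort(paste0("condition absent from plate: ",
                 paste(unknown, collapse = ", ")))
  }
  d <- plate$data
  apo <- d[d$condition == apo_name, ]
  if (nrow(apo) == 0) abort("zero Apo replicates")
  apo_split <- split(apo$value, factor(apo$motif, levels = plate$motifs))
  apo_mean <- vapply(apo_split, mean, numeric(1))
  apo_n <- lengths(apo_split)
  cond_d <- d[d$condition %in% condition, ]
  if (nrow(cond_d) == 0) abort("zero replicates in requested condition(s)")

  out <- summarise(
    group_by(cond_d, .data$motif, .data$condition),
    mean_value = mean(.data$value), n_condition = dplyr::n(),
    values = list(.data$value), .groups = "drop"
  )
  out$n_apo <- as.integer(apo_n[out$motif])
  out$lfc <- unname(log2(out$mean_value + eps) -
                      log2(apo_mean[out$motif] + eps))
  out$p_value <- NA_real_
  testable <- which(out$n_condition >= 2 & out$n_apo >= 2)
  for (i in testable) {
    out$p_value[i] <- welch_p(out$values[[i]], apo_split[[out$motif[i]]],
                              alternative = alternative)
  }
  out$stars <- star_tiers(out$p_value, tiers)
  out <- out[order(match(out$condition, condition),
                   match(out$motif, plate$motifs)), ]
  out[, c("motif", "condition", "lfc", "p_value", "stars",
          "n_condition", "n_apo")]
}

# LFC matrix of the screening fractions: motifs x fractions in sequential
# well order. Returns list(lfc = matrix, index = fraction indices).
fraction_lfc <- function(plate, eps = 1) {
  meta <- plate$conditions[plate$conditions$type == "fraction", ]
  if (nrow(meta) == 0) {
    return(list(lfc = matrix(numeric(0), nrow = length(plate$motifs),
                             dimnames = list(plate$motifs, NULL)),
                index = integer(0)))
  }
  meta <- meta[order(meta$fraction_index), ]
  mod <- modulation(plate, meta$condition, eps = eps)
  m <- matrix(NA_real_, nrow = length(plate$motifs), ncol = nrow(meta),
              dimnames = list(plate$motifs, meta$condition))
  m[cbind(match(mod$motif, plate$motifs),
          match(mod$condition, meta$condition))] <- mod$lfc
  list(lfc = m, index = meta$fraction_index)
}

#' Classify motifs by their response to cortisol and to plant fractions
#'
#' A motif is *GC-responsive* when cortisol modulates it significantly
#' (replicated Welch test at `alpha`), *fraction-responsive* when at least
#' `min_fractions` screening fractions shift it by `|LFC| >= lfc_threshold`
#' (screening wells are single replicates, so hit finding there is
#' threshold-based, never p-value-based). Motifs responding to both are
#' *shared*; to neither, *unresponsive*; to fractions only,
#' *plant-exclusive*.
#'
#' @param plate A [binding_plate()] carrying Apo, Cortisol and fraction
#'   conditions.
#' @param alpha Significance level for the cortisol test (default 0.05).
#' @param lfc_threshold Absolute screening LFC calling a fraction response
#'   (default 1, i.e. a two-fold change).
#' @param min_fractions Minimum number of fractions above threshold
#'   (default 1).
#' @param eps Pseudo-count, as in [modulation()].
#' @return Tibble: `motif`, `class` (one of `GC-responsive`,
#'   `plant-exclusive`, `shared`, `unresponsive`), `cortisol_lfc`,
#'   `cortisol_fold`, `cortisol_p`, `n_active_fractions`,
#'   `max_abs_fraction_lfc`.
#' @export
classify_motifs <- function(plate, alpha = 0.05, lfc_threshold = 1,
                            min_fractions = 1, eps = 1) {
  stopifnot(inherits(plate, "binding_plate"))
  cort <- plate$conditions$condition[plate$conditions$type == "cortisol"]
  if (length(cort) != 1) {
    abort("plate must carry exactly one Cortisol condition for classification")
  }
  cmod <- modulation(plate, cort, eps = eps)
  fl <- fraction_lfc(plate, eps = eps)
  if (ncol(fl$lfc) == 0) {
    abort("plate carries no fraction conditions to classify against")
  }
  n_active <- rowSums(abs(fl$lfc) >= lfc_threshold, na.rm = TRUE)
  max_abs <- apply(abs(fl$lfc), 1, max, na.rm = TRUE)
  gc_hit <- !is.na(cmod$p_value) & cmod$p_value < alpha
  frac_hit <- n_active[cmod$motif] >= min_fractions
  tibble(
    motif = cmod$motif,
    class = dplyr::case_when(
      gc_hit & frac_hit ~ "shared",
      gc_hit ~ "GC-responsive",
      frac_hit ~ "plant-exclusive",
      TRUE ~ "unresponsive"
    ),
    cortisol_lfc = cmod$lfc,
    cortisol_fold = 2^cmod$lfc,
    cortisol_p = cmod$p_value,
    n_active_fractions = as.integer(n_active[cmod$motif]),
    max_abs_fraction_lfc = as.numeric(max_abs[cmod$motif])
  )
}

# Minimal number of successive-difference sign violations over all
# rise-then-fall splits of a profile. 0 means strictly unimodal.
unimodality_violations <- function(profile) {
  d <- diff(profile)
  n <- length(d)
  if (n == 0) return(0L)
  rising_bad <- cumsum(c(0L, as.integer(d <= 0)))       # d[1..k] must be > 0
  falling_bad <- rev(cumsum(c(0L, rev(as.integer(d >= 0)))))  # d[k+1..n] < 0
  min(rising_bad + falling_bad)
}

#' Detect bell-shaped active fraction clusters
#'
#' Fractions of interest sit on a continuous activity gradient produced by
#' chromatographic separation: a bioactive metabolite elutes over adjacent
#' fractions, so its signal rises to an apex and falls again. For each motif
#' of the requested classes this finds maximal contiguous runs of fractions
#' with `|LFC| >= lfc_threshold`; runs of at least `min_len` fractions whose
#' absolute-LFC profile is unimodal (rise-then-fall sign pattern of
#' successive differences, allowing `tolerance` violations) are kept, and
#' overlapping runs across motifs are merged into one cluster whose motif
#' set records the contributors. The apex is the fraction maximising the
#' mean absolute LFC over the cluster's motifs.
#'
#' @param plate A screening [binding_plate()].
#' @param min_len Minimum cluster length in fractions (default 3).
#' @param lfc_threshold Absolute LFC defining an active fraction (default 1).
#' @param tolerance Allowed unimodality violations per run (default 1).
#' @param motif_classes Motif classes searched for clusters; plant-exclusive
#'   and shared motifs by default.
#' @param classification Optional precomputed [classify_motifs()] table.
#' @param eps Pseudo-count, as in [modulation()].
#' @return Tibble of class `active_clusters`: `plant_id`, `cluster_id`,
#'   `start`, `apex`, `end` (sequential fraction indices, inclusive),
#'   `start_well`, `apex_well`, `end_well`, `n_fractions`, `peak_lfc`,
#'   `motifs` (list of contributing motifs), `directions` (list, sign of the
#'   apex LFC per motif), `profile` (list of per-fraction mean `|LFC|`).
#'   Zero rows when nothing is found.
#' @export
detect_clusters <- function(plate, min_len = 3, lfc_threshold = 1,
                            tolerance = 1,
                            motif_classes = c("plant-exclusive", "shared"),
                            classification = NULL, eps = 1) {
  stopifnot(inherits(plate, "binding_plate"), min_len >= 1)
  if (is.null(classification)) {
    classification <- classify_motifs(plate, lfc_threshold = lfc_threshold,
                                      eps = eps)
  }
  motifs <- classification$motif[classification$class %in% motif_classes]
  empty <- tibble(
    plant_id = character(0), cluster_id = integer(0),
    start = integer(0), apex = integer(0), end = integer(0),
    start_well = character(0), apex_well = character(0),
    end_well = character(0), n_fractions = integer(0),
    peak_lfc = numeric(0), motifs = list(), directions = list(),
    profile = list()
  )
  class(empty) <- c("active_clusters", class(tibble()))
  if (length(motifs) == 0) return(empty)

  fl <- fraction_lfc(plate, eps = eps)
  if (ncol(fl$lfc) == 0) return(empty)
  # position p (column) holds fraction index fl$index[p]; runs operate on
  # consecutive *indices*, so split runs across gaps in the well sequence
  runs <- list()
  for (m in motifs) {
    v <- fl$lfc[m, ]
    act <- !is.na(v) & abs(v) >= lfc_threshold
    if (!any(act)) next
    pos <- which(act)
    grp <- cumsum(c(1L, diff(fl$index[pos]) != 1L))
    for (g in split(pos, grp)) {
      if (length(g) < min_len) next
      if (unimodality_violations(abs(v[g])) > tolerance) next
      runs[[length(runs) + 1L]] <- list(
        motif = m, start = fl$index[g[1]], end = fl$index[g[length(g)]]
      )
    }
  }
  if (length(runs) == 0) return(empty)

  starts <- vapply(runs, `[[`, integer(1), "start")
  ends <- vapply(runs, `[[`, integer(1), "end")
  o <- order(starts, ends)
  # merge overlapping [start, end] intervals across motifs
  cluster_id <- integer(length(runs))
  cur <- 0L
  cur_end <- -Inf
  for (i in o) {
    if (starts[i] > cur_end) {
      cur <- cur + 1L
      cur_end <- ends[i]
    } else {
      cur_end <- max(cur_end, ends[i])
    }
    cluster_id[i] <- cur
  }

  rows <- purrr::map_dfr(seq_len(cur), function(cid) {
    members <- which(cluster_id == cid)
    c_start <- min(starts[members])
    c_end <- max(ends[members])
    c_motifs <- unique(vapply(runs[members], `[[`, "", "motif"))
    cols <- fl$index >= c_start & fl$index <= c_end
    sub <- fl$lfc[c_motifs, cols, drop = FALSE]
    prof <- colMeans(abs(sub), na.rm = TRUE)
    apex_idx <- fl$index[cols][which.max(prof)]
    dir_at_apex <- sign(fl$lfc[c_motifs, which(fl$index == apex_idx),
                               drop = TRUE])
    tibble(
      plant_id = plate$plant_id, cluster_id = cid,
      start = c_start, apex = apex_idx, end = c_end,
      start_well = index_well(c_start), apex_well = index_well(apex_idx),
      end_well = index_well(c_end),
      n_fractions = c_end - c_start + 1L,
      peak_lfc = max(abs(sub), na.rm = TRUE),
      motifs = list(c_motifs),
      directions = list(stats::setNames(as.numeric(dir_at_apex), c_motifs)),
      profile = list(tibble(index = fl$index[cols],
                            well = index_well(fl$index[cols]),
                            mean_abs_lfc = as.numeric(prof)))
    )
  })
  class(rows) <- c("active_clusters", class(tibble()))
  rows
}

#' Confirm a cluster apex with replicated measurements
#'
#' The apex fraction of a screening cluster is retested with technical
#' replicates; per-motif modulation against Apo is computed and the cluster
#' counts as confirmed when at least one of its contributing motifs is
#' significant at `alpha` in the direction seen at the screening apex.
#'
#' @param plate_confirmation A replicated [binding_plate()] containing the
#'   apex fraction condition (same well label).
#' @param cluster One row of a [detect_clusters()] result.
#' @param alpha Significance level (default 0.05).
#' @param eps Pseudo-count, as in [modulation()].
#' @return Tibble of [modulation()] results for the apex condition over all
#'   plate motifs, with `in_cluster`, `expected_direction` and `supports`
#'   columns; attribute `confirmed` (logical) summarises the call, also
#'   exposed via [is_confirmed()].
#' @export
confirm_apex <- function(plate_confirmation, cluster, alpha = 0.05, eps = 1) {
  stopifnot(inherits(plate_confirmation, "binding_plate"))
  cluster <- as_tibble(cluster)
  stopifnot(nrow(cluster) == 1)
  apex_cond <- index_well(cluster$apex)
  meta <- plate_confirmation$conditions
  if (!apex_cond %in% meta$condition) {
    abort(paste0("apex fraction ", apex_cond,
                 " absent from confirmation plate"))
  }
  mod <- modulation(plate_confirmation, apex_cond, eps = eps)
  if (all(mod$n_condition < 3)) {
    abort("confirmation plate must carry >= 3 replicates of the apex fraction")
  }
  dirs <- cluster$directions[[1]]
  mod$in_cluster <- mod$motif %in% cluster$motifs[[1]]
  mod$expected_direction <- as.numeric(dirs[mod$motif])
  mod$supports <- mod$in_cluster &
    !is.na(mod$p_value) & mod$p_value < alpha &
    sign(mod$lfc) == mod$expected_direction
  attr(mod, "confirmed") <- any(mod$supports)
  mod
}

#' @rdname confirm_apex
#' @param x A [confirm_apex()] result.
#' @export
is_confirmed <- function(x) isTRUE(attr(x, "confirmed"))

#' Call competitive inhibition from a motif-spiking experiment
#'
#' If every responsive coregulator motif binds the receptor through one
#' shared surface, spiking the assay solution with one strong-binding motif
#' competes the receptor away from *all* immobilized responsive motifs. Per
#' responsive motif, binding under the spiked condition is compared with the
#' unspiked stimulus by a one-sided Welch test (reduction); the call is
#' `"+"` when all responsive motifs are significantly reduced, `"-"` when
#' fewer than `partial_band[1]` (default one half) of them are, and `"±"`
#' in between.
#'
#' @param activity_plate Replicated [binding_plate()] carrying the stimulus
#'   condition (a cortisol control or an apex fraction well).
#' @param spiked_plate Plate carrying the spiked condition
#'   `<stimulus>+<spiked_motif>`; defaults to `activity_plate`.
#' @param stimulus Condition name of the unspiked stimulus (e.g. `"C4"` or
#'   `"Cortisol"`).
#' @param spiked_motif Identifier of the motif added in solution.
#' @param responsive Optional character vector of responsive motifs;
#'   defaults to the motifs significantly *increased* by the stimulus versus
#'   Apo on the activity plate (two-sided test at `alpha`) with an induction
#'   of at least `lfc_threshold` — the effect-size floor keeps barely
#'   fluctuating motifs out of the responsive set.
#' @param lfc_threshold Minimum stimulus LFC for a motif to count as
#'   responsive (default 1).
#' @param alpha Significance level (default 0.05).
#' @param partial_band Proportion band of reduced motifs mapped to the
#'   intermediate `"±"` call (default `[0.5, 1)`).
#' @param eps Pseudo-count, as in [modulation()].
#' @return List of class `inhibition_call`: `plant_id`, `fraction`
#'   (stimulus), `spiked_motif`, `call` (`+`, `-`, `±`), `prop_reduced`,
#'   `outcomes` (per-motif tibble with one-sided p-values).
#' @export
inhibition_call <- function(activity_plate, spiked_plate = activity_plate,
                            stimulus, spiked_motif, responsive = NULL,
                            alpha = 0.05, lfc_threshold = 1,
                            partial_band = c(0.5, 1), eps = 1) {
  stopifnot(inherits(activity_plate, "binding_plate"),
            inherits(spiked_plate, "binding_plate"))
  if (!stimulus %in% activity_plate$conditions$condition) {
    abort(paste0("stimulus condition '", stimulus,
                 "' absent from activity plate"))
  }
  spike_cond <- paste0(stimulus, "+", spiked_motif)
  if (!spike_cond %in% spiked_plate$conditions$condition) {
    abort(paste0("spiked condition '", spike_cond,
                 "' absent from spiked plate"))
  }
  if (is.null(responsive)) {
    act <- modulation(activity_plate, stimulus, eps = eps)
    responsive <- act$motif[!is.na(act$p_value) & act$p_value < alpha &
                              act$lfc >= lfc_threshold]
  }
  if (length(responsive) == 0) abort("nothing to inhibit: no responsive motifs")

  d_act <- activity_plate$data
  d_spk <- spiked_plate$data
  outcomes <- purrr::map_dfr(responsive, function(m) {
    unspiked <- d_act$value[d_act$motif == m & d_act$condition == stimulus]
    spiked <- d_spk$value[d_spk$motif == m & d_spk$condition == spike_cond]
    if (length(spiked) == 0) {
      abort(paste0("spiked condition lacks motif ", m))
    }
    tibble(
      motif = m,
      mean_unspiked = mean(unspiked),
      mean_spiked = mean(spiked),
      lfc_spiked = log2(mean(spiked) + eps) - log2(mean(unspiked) + eps),
      p_one_sided = welch_p(spiked, unspiked, alternative = "less")
    )
  })
  outcomes$reduced <- !is.na(outcomes$p_one_sided) &
    outcomes$p_one_sided < alpha
  prop <- mean(outcomes$reduced)
  call <- if (all(outcomes$reduced)) "+"
  else if (prop < partial_band[1]) "-"
  else "±"
  structure(
    list(plant_id = activity_plate$plant_id, fraction = stimulus,
         spiked_motif = spiked_motif, call = call, prop_reduced = prop,
         n_responsive = length(responsive), outcomes = outcomes),
    class = "inhibition_call"
  )
}

#' @export
print.inhibition_call <- function(x, ...) {
  cat("<inhibition_call> ", x$plant_id, " ", x$fraction, " spiked with ",
      x$spiked_motif, ": '", x$call, "' (",
      sum(x$outcomes$reduced), "/", x$n_responsive,
      " responsive motifs reduced)\n", sep = "")
  invisible(x)
}

#' @export
tidy.inhibition_call <- function(x, ...) {
  tibble(plant = x$plant_id, fraction = x$fraction,
         spiked_motif = x$spiked_motif, call = x$call,
         prop_reduced = x$prop_reduced, n_responsive = x$n_responsive)
}

#' Fraction-profile plot for selected motifs
#'
#' Screening LFC of each motif across the sequential fractions, the standard
#' view for spotting bell-shaped activity gradients.
#'
#' @param plate A [binding_plate()].
#' @param motifs Motifs to draw (defaults to all).
#' @param eps Pseudo-count, as in [modulation()].
#' @return A ggplot object.
#' @export
plot_fraction_profile <- function(plate, motifs = NULL, eps = 1) {
  fl <- fraction_lfc(plate, eps = eps)
  if (is.null(motifs)) motifs <- rownames(fl$lfc)
  long <- tibble(
    motif = rep(motifs, each = length(fl$index)),
    index = rep(fl$index, length(motifs)),
    lfc = as.vector(t(fl$lfc[motifs, , drop = FALSE]))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$index, y = .data$lfc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~motif, scales = "free_y") +
    ggplot2::labs(x = "fraction index (row-major well order)",
                  y = "LFC vs Apo")
}
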