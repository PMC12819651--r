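# Frequency metrics and iterative Pareto-front (non-dominated sorting) ranks.

#' Per-drug frequency and relative frequency within a selection
#'
#' For every botanical drug occurring in at least one selected recipe:
#' `f1` is the number of selected recipes containing the drug, `db_total` the
#' number of recipes in the *whole* corpus containing it, and
#' `f2 = 100 * f1 / db_total` the relative frequency in percent — a
#' specificity measure, always normalised against the full corpus, never the
#' selection. A drug counts once per recipe (recipe-level presence).
#'
#' @param corpus A [corpus()].
#' @param selection A `dataset_selection` derived from the same corpus (or a
#'   character vector of recipe ids).
#' @return Tibble `drug`, `f1`, `db_total`, `f2`, sorted by decreasing `f1`.
#'   `f2` is kept at full precision; round only for reporting.
#' @export
compute_frequencies <- function(corpus, selection) {
  stopifnot(inherits(corpus, "corpus"))
  ids <- if (inherits(selection, "dataset_selection")) {
    selection$recipe_ids
  } else as.character(selection)
  missing_ids <- setdiff(ids, corpus$recipes$recipe_id)
  if (length(missing_ids) > 0) {
    abort(paste0("selection references recipes absent from corpus: ",
                 paste(utils::head(missing_ids, 3), collapse = ", ")))
  }
  long <- tibble(
    recipe_id = rep(corpus$recipes$recipe_id,
                    lengths(corpus$recipes$ingredients)),
    drug = unlist(corpus$recipes$ingredients)
  )
  totals <- dplyr::count(long, .data$drug, name = "db_total")
  sel <- dplyr::count(long[long$recipe_id %in% ids, ], .data$drug, name = "f1")
  out <- left_join(sel, totals, by = "drug")
  out$f2 <- 100 * out$f1 / out$db_total
  arrange(out, dplyr::desc(.data$f1), .data$drug)
}

#' Apply the minimum-occurrence threshold
#'
#' Drops drugs occurring fewer than `min_count` times in the selection, then
#' recipes whose retained-ingredient set becomes empty, then search terms left
#' with no linked recipe. Returns the filtered frequency table, the reduced
#' selection, and an accounting of every drop so that
#' `n recipes retained = n selected - n dropped` can be audited.
#'
#' @param freqs Output of [compute_frequencies()].
#' @param corpus The corpus the selection came from.
#' @param selection The `dataset_selection` the frequencies were computed on.
#' @param min_count Minimum `f1` to retain a drug (default 10).
#' @return List of class `threshold_result`: `points` (filtered tibble),
#'   `selection` (reduced `dataset_selection`), `dropped_drugs`,
#'   `dropped_recipes`, `dropped_terms` (character vectors) and `counts`
#'   (one-row tibble of before/after sizes).
#' @export
apply_threshold <- function(freqs, corpus, selection, min_count = 10) {
  stopifnot(inherits(corpus, "corpus"),
            inherits(selection, "dataset_selection"),
            min_count >= 1)
  keep <- freqs$f1 >= min_count
  if (!any(keep)) abort("empty analysis set: all drugs fall below min_count")
  dropped_drugs <- freqs$drug[!keep]
  points <- freqs[keep, ]

  idx <- match(selection$recipe_ids, corpus$recipes$recipe_id)
  has_retained <- vapply(corpus$recipes$ingredients[idx],
                         function(ing) any(ing %in% points$drug), logical(1))
  dropped_recipes <- selection$recipe_ids[!has_retained]
  kept_ids <- selection$recipe_ids[has_retained]

  kept_idx <- match(kept_ids, corpus$recipes$recipe_id)
  live_terms <- unique(unlist(corpus$recipes$indications[kept_idx]))
  term_alive <- selection$terms_used$term %in% live_terms
  dropped_terms <- selection$terms_used$term[!term_alive]

  reduced <- new_selection(selection$name, kept_ids,
                           selection$terms_used[term_alive, ])
  if (!is.null(selection$attribution)) {
    reduced$attribution <-
      selection$attribution[selection$attribution$recipe_id %in% kept_ids, ]
  }
  structure(
    list(points = points, selection = reduced,
         dropped_drugs = dropped_drugs,
         dropped_recipes = dropped_recipes,
         dropped_terms = dropped_terms,
         counts = tibble(
           min_count = min_count,
           drugs_before = nrow(freqs), drugs_after = nrow(points),
           recipes_before = length(selection$recipe_ids),
           recipes_after = length(kept_ids),
           terms_before = nrow(selection$terms_used),
           terms_after = nrow(reduced$terms_used)
         )),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("<threshold_result> min_count =", x$counts$min_count, "\n")
  cat("  drugs:  ", x$counts$drugs_before, "->", x$counts$drugs_after, "\n")
  cat("  recipes:", x$counts$recipes_before, "->", x$counts$recipes_after, "\n")
  cat("  terms:  ", x$counts$terms_before, "->", x$counts$terms_after, "\n")
  invisible(x)
}

# Non-dominated front of unique (f1, f2) points, both objectives maximized.
# Sorted by f1 desc then f2 desc, a point is on the front iff its f2 exceeds
# the running maximum of f2 over all earlier (weakly f1-better) points.
front_of <- function(f1, f2) {
  o <- order(-f1, -f2)
  on_front <- logical(length(f1))
  best_f2 <- -Inf
  for (i in o) {
    if (f2[i] > best_f2) {
      on_front[i] <- TRUE
      best_f2 <- f2[i]
    }
  }
  on_front
}

#' Assign iterative Pareto-front ranks
#'
#' Point *a* dominates *b* when `a$f1 >= b$f1` and `a$f2 >= b$f2` with at
#' least one inequality strict; both objectives are maximized. Rank 1 is the
#' set of non-dominated points; removing it and repeating yields rank 2, and
#' so on until `max_rank` fronts are peeled or the points are exhausted.
#' Points with identical `(f1, f2)` share a rank. Points beyond `max_rank`
#' keep `rank = NA`.
#'
#' @param points Tibble with columns `drug`, `f1`, `f2` (e.g. from
#'   [compute_frequencies()] or a `threshold_result$points`).
#' @param max_rank Number of fronts to peel (default 3). Use `Inf` to rank
#'   every point.
#' @param dataset_name Stored for reporting.
#' @return Object of class `pareto_result`: list with `points` (the input
#'   plus a `rank` column), `dataset_name`, `max_rank`.
#' @export
pareto_ranks <- function(points, max_rank = 3, dataset_name = "dataset") {
  points <- as_tibble(points)
  stopifnot(all(c("drug", "f1", "f2") %in% names(points)), nrow(points) >= 1,
            max_rank >= 1)
  key <- paste(points$f1, points$f2, sep = "\r")
  uni <- !duplicated(key)
  uf1 <- points$f1[uni]
  uf2 <- points$f2[uni]
  ukey <- key[uni]
  urank <- rep(NA_integer_, length(uf1))
  remaining <- rep(TRUE, length(uf1))
  r <- 0L
  while (any(remaining) && r < max_rank) {
    r <- r + 1L
    idx <- which(remaining)
    on <- front_of(uf1[idx], uf2[idx])
    urank[idx[on]] <- r
    remaining[idx[on]] <- FALSE
  }
  points$rank <- urank[match(key, ukey)]
  points <- arrange(points, .data$rank, dplyr::desc(.data$f1), .data$drug)
  structure(
    list(points = points, dataset_name = dataset_name,
         max_rank = if (is.finite(max_rank)) as.integer(max_rank) else r),
    class = "pareto_result"
  )
}

#' @export
print.pareto_result <- function(x, ...) {
  tab <- table(x$points$rank)
  cat("<pareto_result '", x$dataset_name, "'> ", nrow(x$points),
      " drugs; front sizes: ",
      paste(sprintf("rank %s = %d", names(tab), as.integer(tab)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname pareto_ranks
#' @param x A `pareto_result`.
#' @param ... Unused.
#' @return `tidy()`: the ranked points tibble with `f2` rounded to one
#'   decimal for reporting (ranks were computed at full precision).
#' @export
tidy.pareto_result <- function(x, ...) {
  out <- x$points
  out$f2 <- round(out$f2, 1)
  out$dataset <- x$dataset_name
  out
}

#' @rdname pareto_ranks
#' @return `glance()`: one-row tibble with the number of drugs, the number of
#'   ranked drugs and per-front counts.
#' @export
glance.pareto_result <- function(x, ...) {
  ranked <- x$points$rank[!is.na(x$points$rank)]
  out <- tibble(dataset = x$dataset_name,
                n_drugs = nrow(x$points),
                n_ranked = length(ranked),
                max_rank = x$max_rank)
  for (r in seq_len(x$max_rank)) out[[paste0("n_rank", r)]] <- sum(ranked == r)
  out
}

#' Pareto scatter plot with front polylines
#'
#' Frequency against relative frequency, one point per drug; ranked fronts
#' drawn as step polylines.
#'
#' @param object A `pareto_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pareto_result <- function(object, ...) {
  pts <- object$points
  pts$front <- ifelse(is.na(pts$rank), "unranked", paste("rank", pts$rank))
  fronts <- pts[!is.na(pts$rank), ]
  fronts <- arrange(fronts, .data$rank, .data$f1, dplyr::desc(.data$f2))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$f1, y = .data$f2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$front)) +
    ggplot2::geom_step(data = fronts, direction = "vh",
                       ggplot2::aes(group = .data$rank)) +
    ggplot2::labs(x = "frequency (f1)", y = "relative frequency (f2, %)",
                  title = object$dataset_name, colour = NULL)
}

#' Cross-subset rank matrix for joint-dataset candidates
#'
#' Rows are the drugs ranked `1..max_rank` in the joint dataset; columns the
#' subsets, cells the drug's Pareto rank there (`NA` when the drug is absent
#' from — or unranked in — that subset). An optional annotation table joins a
#' literature classification per drug.
#'
#' @param joint `pareto_result` for the joint dataset.
#' @param subsets Named list of `pareto_result`s.
#' @param annotation Optional tibble `drug`, `classification`.
#' @return Tibble of class `rank_matrix`: `drug`, `joint`, one column per
#'   subset, and `classification` if annotation was given.
#' @export
rank_matrix <- function(joint, subsets, annotation = NULL) {
  stopifnot(inherits(joint, "pareto_result"))
  cand <- joint$points[!is.na(joint$points$rank), c("drug", "rank")]
  out <- rename(cand, joint = "rank")
  for (nm in names(subsets)) {
    sub <- subsets[[nm]]$points[, c("drug", "rank")]
    out <- left_join(out, rename(sub, !!nm := "rank"), by = "drug")
  }
  if (!is.null(annotation)) {
    annotation <- as_tibble(annotation)
    unknown <- setdiff(annotation$drug, out$drug)
    if (length(unknown) > 0) {
      warn(paste0("annotation names drugs absent from candidates (ignored): ",
                  paste(utils::head(unknown, 3), collapse = ", ")))
    }
    out <- left_join(out, annotation[annotation$drug %in% out$drug, ],
                     by = "drug")
  }
  class(out) <- c("rank_matrix", class(tibble()))
  out
}

#' Heatmap of the cross-subset rank matrix
#'
#' @param object A [rank_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rank_matrix <- function(object, ...) {
  value_cols <- setdiff(names(object), c("drug", "classification"))
  long <- tidyr::pivot_longer(as_tibble(object), dplyr::all_of(value_cols),
                              names_to = "dataset", values_to = "rank")
  long$dataset <- factor(long$dataset, levels = value_cols)
  long$drug <- factor(long$drug, levels = rev(object$drug))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$dataset, y = .data$drug,
                                     fill = factor(.data$rank))) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$rank), na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "PF rank")
}

#' Write ranked points or a rank matrix to CSV
#'
#' @param x A `pareto_result` or `rank_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pareto_csv <- function(x, path) {
  if (inherits(x, "pareto_result")) {
    readr::write_csv(tidy.pareto_result(x), path)
  } else {
    readr::write_csv(as_tibble(x), path)
  }
  invisible(path)
}
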