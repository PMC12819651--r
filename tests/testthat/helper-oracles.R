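# Independent oracles and in-code fixtures shared across the suite.

# O(n^2) repeated non-dominated-set peeling, independent of the package's
# sort-scan implementation: a point is dominated when some other remaining
# point is weakly better in both objectives and strictly better in one.
brute_force_pareto <- function(f1, f2, max_rank = Inf) {
  n <- length(f1)
  rank <- rep(NA_integer_, n)
  remaining <- rep(TRUE, n)
  r <- 0L
  while (any(remaining) && r < max_rank) {
    r <- r + 1L
    idx <- which(remaining)
    nd <- vapply(idx, function(i) {
      j <- idx[idx != i]
      !any(f1[j] >= f1[i] & f2[j] >= f2[i] &
             (f1[j] > f1[i] | f2[j] > f2[i]))
    }, logical(1))
    rank[idx[nd]] <- r
    remaining[idx[nd]] <- FALSE
  }
  rank
}

# Tiny handmade corpus: 5 recipes, 2 arthritis (1 main, 1 orbit) + 1 skin
# search term plus background indications.
mini_corpus <- function() {
  corpus(tibble::tibble(
    recipe_id = paste0("r", 1:5),
    title = paste("recipe", 1:5),
    source_id = "ms1",
    indications = list(
      c("hexi feng"),                 # main arthritis
      c("jingu tong", "other ill"),   # orbit arthritis
      c("yangmei chuang"),            # skin
      c("hexi feng", "yangmei chuang"), # both categories
      c("other ill")                  # background only
    ),
    ingredients = list(
      c("ginger", "licorice"),
      c("ginger"),
      c("smilax"),
      c("smilax", "licorice"),
      c("licorice")
    )
  ))
}

mini_terms <- function() {
  search_terms(tibble::tibble(
    term = c("hexi feng", "jingu tong", "yangmei chuang"),
    transliteration = c("hexi feng", "jingu tong", "yangmei chuang"),
    category = c("arthritis", "arthritis", "skin"),
    granularity = c("main", "orbit", "none")
  ))
}

# Three stacked anti-diagonal fronts with 9, 11 and 12 points. Points on the
# line f1 + f2 = S are mutually non-dominated; a point on a lower line is
# dominated by any higher-line point whose f1 lies within [f1, f1 + dS].
# The x-grids are chosen so every inner point has such a dominator.
front_fixture <- function() {
  x1 <- c(20 + 12 * 0:7, 125)          # 9 points,  S = 1000
  x2 <- c(15 + 10 * 0:9, 120)          # 11 points, S = 900
  x3 <- 8 + 10 * 0:11                  # 12 points, S = 800
  tibble::tibble(
    drug = sprintf("d%02d", seq_len(32)),
    f1 = c(x1, x2, x3),
    f2 = c(1000 - x1, 900 - x2, 800 - x3),
    true_rank = rep(1:3, c(9, 11, 12))
  )
}

# Plate spec for a clean null plate: no GC effect, no clusters.
null_plate_spec <- function(seed, fractions = 1:96, fraction_reps = 1) {
  plate_spec(plant_id = paste0("null", seed), gc_folds = NULL,
             clusters = NULL, fractions = fractions,
             fraction_reps = fraction_reps, seed = seed)
}

# Deterministic handmade plate: values are exact means, replicated with no
# noise, so modulation arithmetic can be asserted exactly.
exact_plate <- function(apo = c(A = 100, B = 200),
                        conditions = list(stim = c(A = 100, B = 400)),
                        reps = 3) {
  rows <- list()
  add <- function(cond, means) {
    for (rep in seq_len(reps)) {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        motif = names(means), condition = cond, replicate = rep,
        value = unname(means))
    }
  }
  add("Apo", apo)
  for (cn in names(conditions)) add(cn, conditions[[cn]])
  binding_plate(dplyr::bind_rows(rows), plant_id = "exact")
}
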