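test_that("corpus generation is deterministic in the seed", {
  spec <- corpus_spec(n_recipes = 300, seed = 5)
  a <- generate_corpus(spec)
  b <- generate_corpus(corpus_spec(n_recipes = 300, seed = 5))
  expect_true(corpus_equal(a$corpus, b$corpus))
  expect_identical(a$truth$planted$db_total, b$truth$planted$db_total)
  c2 <- generate_corpus(corpus_spec(n_recipes = 300, seed = 6))
  expect_false(corpus_equal(a$corpus, c2$corpus))
})

test_that("a fully in-set specific drug reaches 100% relative frequency", {
  st <- default_search_terms()
  spec <- corpus_spec(
    n_recipes = 800,
    planted_specific = tibble::tibble(
      drug = "pure specialist",
      target = list(st$term),
      in_rate = 1.0, out_rate = 0.0),
    planted_common = tibble::tibble(drug = "everywhere", rate = 0.3),
    seed = 9)
  g <- generate_corpus(spec)
  subs <- build_subsets(g$corpus, g$terms)
  f <- compute_frequencies(g$corpus, subs$all_terms)
  expect_equal(f$f2[f$drug == "pure specialist"], 100)
  expect_equal(f$f1[f$drug == "pure specialist"],
               length(subs$all_terms$recipe_ids))
})

test_that("infeasible planted rates are rejected", {
  spec <- corpus_spec(
    n_recipes = 200,
    planted_specific = tibble::tibble(
      drug = "ghost", target = list("arth main 01"),
      in_rate = 0.001, out_rate = 0),
    seed = 2)
  expect_error(generate_corpus(spec), "infeasible planted rate")
  expect_error(corpus_spec(planted_common = tibble::tibble(
    drug = "x", rate = 1.5)), "rates must lie")
  expect_error(corpus_spec(
    planted_specific = tibble::tibble(drug = "a", target = list("t"),
                                      in_rate = .5, out_rate = 0),
    planted_common = tibble::tibble(drug = "a", rate = .1)),
    "disjoint")
})

test_that("frequency and relative frequency are inversely related", {
  rho <- vapply(1:8, function(seed) {
    g <- generate_corpus(corpus_spec(n_recipes = 1500, seed = seed))
    subs <- build_subsets(g$corpus, g$terms)
    f <- compute_frequencies(g$corpus, subs$all_terms)
    stats::cor(f$f1, f$f2, method = "spearman")
  }, numeric(1))
  expect_true(all(rho < 0))
})

test_that("planted truth counts match what the corpus actually contains", {
  g <- generate_corpus(corpus_spec(n_recipes = 600, seed = 13))
  long <- tibble::tibble(
    recipe_id = rep(g$corpus$recipes$recipe_id,
                    lengths(g$corpus$recipes$ingredients)),
    drug = unlist(g$corpus$recipes$ingredients))
  for (i in seq_len(nrow(g$truth$planted))) {
    row <- g$truth$planted[i, ]
    expect_equal(sum(long$drug == row$drug), row$db_total)
  }
})

test_that("plate generation is deterministic and the null plate is flat", {
  sp <- plate_spec(fractions = 1:10, seed = 3)
  expect_true(plate_equal(generate_plate(sp)$plate,
                          generate_plate(sp)$plate))
  sp2 <- plate_spec(fractions = 1:10, seed = 4)
  expect_false(plate_equal(generate_plate(sp)$plate,
                           generate_plate(sp2)$plate))
  null <- generate_plate(null_plate_spec(seed = 5))
  expect_true(all(null$truth$true_lfc == 0))
  m <- modulation(null$plate, index_well(1:96))
  expect_lt(max(abs(m$lfc)), 1)   # noise never reaches the hit threshold
})

test_that("overlapping planted clusters on one motif are rejected unless merged", {
  cl2 <- list(
    list(motifs = "PELP1", center = 30, width = 3, peak_lfc = 2),
    list(motifs = "PELP1", center = 33, width = 3, peak_lfc = 2))
  expect_error(plate_spec(clusters = cl2), "overlapping planted clusters")
  expect_s3_class(plate_spec(clusters = cl2, allow_merge = TRUE),
                  "plate_spec")
})

test_that("five planted clusters over four plants span their recorded fractions", {
  # one plant with two clusters, three with one each
  defs <- list(
    list(plant = "plant A", clusters = list(
      list(motifs = "NCOR2", center = 30, width = 2.2, peak_lfc = 2.5),
      list(motifs = "PELP1", center = 65, width = 1.8, peak_lfc = 2.5))),
    list(plant = "plant B", clusters = list(
      list(motifs = "PELP1", center = 28, width = 2.2, peak_lfc = 2.5))),
    list(plant = "plant C", clusters = list(
      list(motifs = "DHX30", center = 50, width = 2.6, peak_lfc = 2.2))),
    list(plant = "plant D", clusters = list(
      list(motifs = "IKBB", center = 80, width = 2.2, peak_lfc = 2.5))))
  total_detected <- 0
  total_truth <- 0
  n_clusters <- 0
  for (i in seq_along(defs)) {
    g <- generate_plate(plate_spec(plant_id = defs[[i]]$plant,
                                   clusters = defs[[i]]$clusters,
                                   gc_folds = c(NCOA1 = 1200),
                                   seed = 100 + i))
    cl <- detect_clusters(g$plate)
    n_clusters <- n_clusters + nrow(cl)
    total_detected <- total_detected + sum(cl$n_fractions)
    total_truth <- total_truth + sum(g$truth$clusters$n_fractions)
    for (j in seq_len(nrow(cl))) {
      k <- which.min(abs(g$truth$clusters$apex - cl$apex[j]))
      expect_lte(abs(cl$start[j] - g$truth$clusters$start[k]), 1)
      expect_lte(abs(cl$end[j] - g$truth$clusters$end[k]), 1)
    }
  }
  expect_equal(n_clusters, 5)
  expect_lte(abs(total_detected - total_truth), 5)  # one fraction per boundary
})

test_that("a planted 1200-fold GC motif classifies as GC-responsive above 1000-fold", {
  g <- generate_plate(plate_spec(gc_folds = c(NCOA1 = 1200),
                                 clusters = NULL, fractions = 1:10,
                                 seed = 17))
  cls <- classify_motifs(g$plate)
  expect_equal(cls$class[cls$motif == "NCOA1"], "GC-responsive")
  expect_gt(cls$cortisol_fold[cls$motif == "NCOA1"], 1000)
})
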