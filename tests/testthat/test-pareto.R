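test_that("frequencies count recipe-level presence against whole-corpus totals", {
  co <- mini_corpus()
  subs <- build_subsets(co, mini_terms())
  f <- compute_frequencies(co, subs$all_terms)
  # licorice: recipes r1, r4 selected of r1, r4, r5 in corpus
  lic <- f[f$drug == "licorice", ]
  expect_equal(lic$f1, 2)
  expect_equal(lic$db_total, 3)
  expect_equal(lic$f2, 100 * 2 / 3)
  # smilax appears only inside the selection -> 100%
  expect_equal(f$f2[f$drug == "smilax"], 100)
  expect_error(compute_frequencies(co, c("nope")), "absent from corpus")
})

test_that("the worked relative frequencies come out at one-decimal precision", {
  # drug a: 11 selected of 13 corpus recipes; drug b: 611 of 6000
  n <- 6000
  ind <- rep(list("background"), n)
  ind[1:611] <- list("target term")
  ing <- rep(list("drug b"), n)
  ing[1:11] <- list(c("drug a", "drug b"))
  ing[612:613] <- list(c("drug a", "drug b"))
  co <- corpus(tibble::tibble(
    recipe_id = sprintf("r%04d", 1:n), indications = ind, ingredients = ing))
  sel <- link_recipes(co, "target term")
  f <- compute_frequencies(co, sel)
  expect_equal(round(f$f2[f$drug == "drug a"], 1), 84.6)
  expect_equal(round(f$f2[f$drug == "drug b"], 1), 10.2)
})

test_that("threshold drops drugs, then emptied recipes, then orphaned terms", {
  # 20 recipes on term "kept": drug bulk everywhere; 4 recipes on term
  # "orphan" contain only rare drugs
  ind <- c(rep(list("kept"), 20), rep(list("orphan"), 4))
  ing <- c(rep(list("bulk"), 20),
           lapply(1:4, function(i) paste0("rare", i)))
  co <- corpus(tibble::tibble(
    recipe_id = paste0("r", 1:24), indications = ind, ingredients = ing))
  terms <- search_terms(tibble::tibble(
    term = c("kept", "orphan"), category = "arthritis",
    granularity = "main"))
  sel <- link_recipes(co, terms)
  f <- compute_frequencies(co, sel)
  thr <- apply_threshold(f, co, sel, min_count = 10)
  expect_setequal(thr$dropped_drugs, paste0("rare", 1:4))
  expect_equal(length(thr$dropped_recipes), 4)
  expect_equal(thr$dropped_terms, "orphan")
  expect_equal(thr$counts$recipes_after,
               thr$counts$recipes_before - length(thr$dropped_recipes))
  # min_count = 1 is the identity
  thr1 <- apply_threshold(f, co, sel, min_count = 1)
  expect_equal(nrow(thr1$points), nrow(f))
  expect_equal(length(thr1$dropped_recipes), 0)
  expect_error(apply_threshold(f, co, sel, min_count = 1000),
               "empty analysis set")
})

test_that("single and extreme points are rank 1", {
  pr <- pareto_ranks(tibble::tibble(drug = "only", f1 = 5, f2 = 50))
  expect_equal(pr$points$rank, 1L)
  # the two printed extremes co-occupy rank 1 when nothing dominates either
  pts <- tibble::tibble(drug = c("specific", "frequent", "mid"),
                        f1 = c(11, 611, 100), f2 = c(84.6, 10.2, 9))
  pr <- pareto_ranks(pts)
  expect_equal(pr$points$rank[pr$points$drug %in% c("specific", "frequent")],
               c(1L, 1L))
  expect_equal(pr$points$rank[pr$points$drug == "mid"], 2L)
})

test_that("coincident points share a rank and NA marks beyond max_rank", {
  pts <- tibble::tibble(drug = c("a", "b", "c", "d"),
                        f1 = c(10, 10, 5, 1), f2 = c(3, 3, 2, 1))
  pr <- pareto_ranks(pts, max_rank = 2)
  expect_equal(pr$points$rank[pr$points$drug %in% c("a", "b")], c(1L, 1L))
  expect_equal(pr$points$rank[pr$points$drug == "c"], 2L)
  expect_true(is.na(pr$points$rank[pr$points$drug == "d"]))
})

test_that("rank assignment matches the brute-force peeling oracle", {
  for (seed in 1:25) {
    withr::with_seed(seed, {
      n <- sample(5:200, 1)
      pts <- tibble::tibble(
        drug = sprintf("d%03d", seq_len(n)),
        f1 = sample(1:40, n, replace = TRUE),   # integer grid forces ties
        f2 = round(stats::runif(n, 0, 100), 1))
    })
    pr <- pareto_ranks(pts, max_rank = Inf)
    expect_equal(pr$points$rank[order(pr$points$drug)],
                 brute_force_pareto(pts$f1, pts$f2)[order(pts$drug)])
  }
})

test_that("dominance structure is invariant under the expected perturbations", {
  withr::with_seed(99, {
    pts <- tibble::tibble(drug = sprintf("d%02d", 1:50),
                          f1 = sample(1:30, 50, replace = TRUE),
                          f2 = stats::runif(50, 0, 100))
  })
  base <- pareto_ranks(pts, max_rank = Inf)
  r1 <- base$points$drug[base$points$rank == 1]

  # adding a point dominated by a rank-1 point leaves rank-1 membership alone
  dom <- base$points[base$points$rank == 1, ][1, ]
  pts2 <- dplyr::bind_rows(pts, tibble::tibble(
    drug = "intruder", f1 = dom$f1 - 1, f2 = dom$f2 - 1))
  new1 <- pareto_ranks(pts2, max_rank = Inf)
  expect_setequal(new1$points$drug[new1$points$rank == 1], r1)

  # scaling an objective by a positive constant preserves every rank
  pts3 <- dplyr::mutate(pts, f1 = f1 * 17)
  pr3 <- pareto_ranks(pts3, max_rank = Inf)
  expect_equal(pr3$points$rank[match(pts$drug, pr3$points$drug)],
               base$points$rank[match(pts$drug, base$points$drug)])
})

test_that("enlarging the selection can only increase f1 and f2", {
  g <- generate_corpus(corpus_spec(n_recipes = 500, seed = 3))
  subs <- build_subsets(g$corpus, g$terms)
  f_small <- compute_frequencies(g$corpus, subs$arthritis_main)
  f_big <- compute_frequencies(g$corpus, subs$arthritis_main_orbit)
  joined <- dplyr::inner_join(f_small, f_big, by = "drug",
                              suffix = c("_s", "_b"))
  expect_true(all(joined$f1_b >= joined$f1_s))
  expect_true(all(joined$f2_b >= joined$f2_s))
})

test_that("cumulative candidate counts are non-decreasing in the rank cutoff", {
  withr::with_seed(7, {
    pts <- tibble::tibble(drug = sprintf("d%02d", 1:80),
                          f1 = sample(1:50, 80, replace = TRUE),
                          f2 = stats::runif(80, 0, 100))
  })
  pr <- pareto_ranks(pts, max_rank = Inf)
  counts <- cumsum(table(pr$points$rank))
  expect_true(all(diff(counts) >= 0))
})

test_that("rank matrix propagates absences and joins annotations", {
  joint <- pareto_ranks(tibble::tibble(
    drug = c("a", "b", "c"), f1 = c(10, 5, 2), f2 = c(10, 50, 90)),
    dataset_name = "all_terms")
  sub1 <- pareto_ranks(tibble::tibble(
    drug = c("a", "b"), f1 = c(4, 3), f2 = c(10, 50)), dataset_name = "skin")
  rm_tab <- rank_matrix(joint, list(skin = sub1))
  expect_true(is.na(rm_tab$skin[rm_tab$drug == "c"]))
  expect_equal(rm_tab$joint, c(1L, 1L, 1L))
  expect_warning(
    rank_matrix(joint, list(skin = sub1),
                annotation = tibble::tibble(drug = c("a", "zz"),
                                            classification = "specific")),
    "absent from candidates")
  # identical points in two subsets give identical cells
  rm2 <- rank_matrix(joint, list(s1 = sub1, s2 = sub1))
  expect_equal(rm2$s1, rm2$s2)
})

test_that("tidy, glance and autoplot expose the ranked results", {
  pr <- pareto_ranks(front_fixture()[, 1:3], max_rank = 3)
  td <- tidy(pr)
  expect_true(all(c("drug", "f1", "f2", "rank", "dataset") %in% names(td)))
  gl <- glance(pr)
  expect_equal(gl$n_rank1 + gl$n_rank2 + gl$n_rank3, 32)
  p <- autoplot(pr)
  expect_s3_class(p, "ggplot")
  rm_tab <- rank_matrix(pr, list())
  expect_s3_class(autoplot(rm_tab), "ggplot")
})
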