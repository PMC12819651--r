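test_that("motif classification separates GC, plant-exclusive and shared motifs", {
  g <- generate_plate(plate_spec(seed = 21))
  cls <- classify_motifs(g$plate)
  expect_equal(cls$class[cls$motif == "NCOA1"], "GC-responsive")
  expect_gt(cls$cortisol_fold[cls$motif == "NCOA1"], 1000)
  expect_equal(cls$class[cls$motif == "PELP1"], "plant-exclusive")
  expect_equal(cls$class[cls$motif == "NCOR2"], "plant-exclusive")
  expect_equal(cls$class[cls$motif == "IKBB"], "shared")
  expect_equal(cls$class[cls$motif == "MOTIF050"], "unresponsive")
})

test_that("a flat plate yields no clusters", {
  g <- generate_plate(null_plate_spec(seed = 31))
  cl <- detect_clusters(g$plate)
  expect_equal(nrow(cl), 0)
})

test_that("a planted Gaussian bump is recovered with its apex", {
  sp <- plate_spec(clusters = list(list(motifs = c("PELP1", "DHX30"),
                                        center = 30, width = 2,
                                        peak_lfc = 2)),
                   gc_folds = c(NCOA1 = 1200), seed = 41)
  g <- generate_plate(sp)
  cl <- detect_clusters(g$plate)
  expect_equal(nrow(cl), 1)
  expect_lte(abs(cl$apex - 30), 1)
  expect_lte(abs(cl$start - g$truth$clusters$start), 1)
  expect_lte(abs(cl$end - g$truth$clusters$end), 1)
  expect_setequal(cl$motifs[[1]], c("PELP1", "DHX30"))
})

test_that("two disjoint bumps on one plant give two clusters", {
  sp <- plate_spec(clusters = list(
    list(motifs = "PELP1", center = 20, width = 2, peak_lfc = 2.5),
    list(motifs = "NCOR2", center = 60, width = 2, peak_lfc = 2.5)),
    gc_folds = c(NCOA1 = 1200), seed = 51)
  g <- generate_plate(sp)
  cl <- detect_clusters(g$plate)
  expect_equal(nrow(cl), 2)
  expect_lte(abs(cl$apex[1] - 20), 1)
  expect_lte(abs(cl$apex[2] - 60), 1)
})

test_that("unimodality screening rejects a two-peaked run", {
  expect_equal(herbfront:::unimodality_violations(c(1, 2, 3, 2, 1)), 0)
  expect_equal(herbfront:::unimodality_violations(c(1, 3, 1, 3, 1)), 1)
  expect_gt(herbfront:::unimodality_violations(c(3, 1, 3, 1, 3, 1, 3)), 1)
  # monotone profiles count as degenerate bells (apex at a boundary)
  expect_equal(herbfront:::unimodality_violations(c(1, 2, 3, 4)), 0)
})

test_that("apex confirmation needs replicates, direction and significance", {
  sp_screen <- plate_spec(seed = 61)
  g <- generate_plate(sp_screen)
  cl <- detect_clusters(g$plate)
  expect_equal(nrow(cl), 1)
  apex <- cl$apex[1]
  conf <- generate_plate(plate_spec(fraction_reps = 3,
                                    fractions = c(apex - 2, apex, apex + 2),
                                    seed = 62))
  res <- confirm_apex(conf$plate, cl[1, ])
  expect_true(is_confirmed(res))
  expect_true(all(res$supports[res$motif %in% c("PELP1", "DHX30", "NCOR2")]))
  # an effect-free confirmation plate does not confirm: every cluster motif
  # sits exactly at its Apo level
  motifs <- g$plate$motifs
  flat <- stats::setNames(rep(100, length(motifs)), motifs)
  conds <- stats::setNames(list(flat), index_well(apex))
  conf_flat <- exact_plate(apo = flat, conditions = conds)
  expect_false(is_confirmed(confirm_apex(conf_flat, cl[1, ])))
  # absent apex fraction is an error
  conf_wrong <- generate_plate(plate_spec(fraction_reps = 3, fractions = 90,
                                          seed = 64))
  expect_error(confirm_apex(conf_wrong$plate, cl[1, ]), "absent")
})

test_that("significance rises and falls across a fraction series spanning a cluster", {
  # series mirroring a gradient: off-cluster, edge, apex, edge, off-cluster
  fr <- c(20, 26, 28, 30, 36)
  conf <- generate_plate(plate_spec(fraction_reps = 3, fractions = fr,
                                    seed = 65))
  m <- modulation(conf$plate, index_well(fr))
  pelp <- m[m$motif == "PELP1", ]
  pelp <- pelp[match(index_well(fr), pelp$condition), ]
  expect_false(pelp$p_value[1] < 0.05 && abs(pelp$lfc[1]) > 1)
  expect_true(pelp$p_value[3] < 0.05)
  expect_true(abs(pelp$lfc[3]) > abs(pelp$lfc[1]))
  expect_true(abs(pelp$lfc[3]) > abs(pelp$lfc[5]))
})

test_that("inhibition calls reproduce the +, -, ± truth table", {
  calls <- vapply(c(full = "full", none = "none", partial = "partial"),
                  function(sc) {
    conf <- generate_plate(plate_spec(
      fraction_reps = 3, fractions = 28,
      spike = list(stimulus = "C4", motif = "PELP1", scenario = sc),
      seed = 71))
    ic <- inhibition_call(conf$plate, stimulus = "C4",
                          spiked_motif = "PELP1")
    ic$call
  }, character(1))
  expect_equal(unname(calls), c("+", "-", "±"))
})

test_that("the partial band boundary maps 60% reduction to ±", {
  # constructed fixture: 5 responsive motifs, exactly 3 reduced
  apo <- stats::setNames(rep(100, 5), paste0("m", 1:5))
  stim <- apo * 8
  spiked <- c(apo[1:3], stim[4:5])
  names(spiked) <- names(apo)
  rows <- list()
  for (rep in 1:3) {
    jitter <- 1 + 0.01 * (rep - 2)
    rows[[length(rows) + 1]] <- tibble::tibble(
      motif = rep(names(apo), 3),
      condition = rep(c("Apo", "C4", "C4+m1"), each = 5),
      replicate = rep,
      value = c(apo, stim, spiked) * jitter)
  }
  p <- binding_plate(dplyr::bind_rows(rows), plant_id = "fixture")
  ic <- inhibition_call(p, stimulus = "C4", spiked_motif = "m1")
  expect_equal(ic$n_responsive, 5)
  expect_equal(ic$prop_reduced, 0.6)
  expect_equal(ic$call, "±")
  expect_equal(tidy(ic)$call, "±")
})

test_that("inhibition with no responsive motifs is an error", {
  g <- generate_plate(null_plate_spec(seed = 81, fractions = 28,
                                      fraction_reps = 3))
  d <- g$plate$data
  spk <- d[d$condition == "C4", ]
  spk$condition <- "C4+PELP1"
  p <- binding_plate(dplyr::bind_rows(d, spk), plant_id = "null")
  expect_error(inhibition_call(p, stimulus = "C4", spiked_motif = "PELP1"),
               "nothing to inhibit")
})
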