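test_that("apposition detection handles the degenerate cases", {
  psd <- data.frame(x_um = c(0, 1), y_um = 0, z_um = 0)
  none <- detect_appositions(psd, psd[0, ])
  expect_equal(sum(none$apposed), 0)
  expect_equal(nrow(none$pairs), 0)
  all_hit <- detect_appositions(psd, psd)
  expect_true(all(all_hit$apposed))
  expect_equal(nrow(all_hit$pairs), 2)
  empty <- detect_appositions(psd[0, ], psd)
  expect_length(empty$apposed, 0)
  expect_error(detect_appositions(psd, psd, lateral_tol_um = -1),
               "lateral_tol_um")
})

test_that("planted pairs are recovered with full recall and no false positives", {
  pts <- generate_puncta_points(60, 1.5, 0.5, 0.05, 0.15, seed = 8,
                                n_distractors = 25, distractor_offset_um = 2)
  det <- detect_appositions(pts$psd, pts$syn)
  expect_setequal(which(det$apposed), pts$matching$psd_idx)   # recall 100%
  expect_equal(nrow(det$pairs), nrow(pts$matching))           # no distractor matches
  expect_true(all(det$pairs$syn_idx <= nrow(pts$matching)))
})

test_that("detection is translation invariant and monotone in tolerance", {
  pts <- generate_puncta_points(40, 2, 0.6, 0.08, 0.2, seed = 15)
  det <- detect_appositions(pts$psd, pts$syn)
  shift <- function(df, v) {
    df$x_um <- df$x_um + v[1]; df$y_um <- df$y_um + v[2]
    df$z_um <- df$z_um + v[3]; df
  }
  det2 <- detect_appositions(shift(pts$psd, c(5, -3, 2)),
                             shift(pts$syn, c(5, -3, 2)))
  expect_equal(det2$apposed, det$apposed)
  expect_equal(det2$pairs$psd_idx, det$pairs$psd_idx)
  # shrinking tolerances can only lose appositions
  tight <- detect_appositions(pts$psd, pts$syn, lateral_tol_um = 0.04,
                              axial_tol_um = 0.1)
  expect_lte(sum(tight$apposed), sum(det$apposed))
  expect_true(all(which(tight$apposed) %in% which(det$apposed)))
})

test_that("greedy matching is one-to-one", {
  psd <- data.frame(x_um = c(0, 0.01), y_um = 0, z_um = 0)
  syn <- data.frame(x_um = 0.005, y_um = 0, z_um = 0)
  det <- detect_appositions(psd, syn)
  expect_equal(nrow(det$pairs), 1)  # one syn point can serve one PSD
  expect_equal(sum(det$apposed), 1)
})

test_that("colocalization_summary pools segments per neuron exactly", {
  tab <- data.frame(
    neuron_id = c("n1", "n1", "n2"),
    animal_id = c("m1", "m1", "m2"),
    group = "g", compartment = "unspecified",
    segment_id = c(1, 2, 1),
    n_psd = c(10, 10, 20), n_apposed = c(5, 5, 10))
  s <- colocalization_summary(tab)
  expect_equal(s$mean_pct, 50)
  expect_equal(s$sem_pct, 0)
  expect_equal(s$n_neurons, 2)
  expect_equal(s$n_animals, 2)

  one <- data.frame(neuron_id = "n1", animal_id = "m1", group = "g",
                    compartment = "unspecified", segment_id = 1:10,
                    n_psd = 10, n_apposed = 4)
  expect_equal(colocalization_summary(one)$mean_pct, 40)
})

test_that("summary is invariant to row order and segment partitioning", {
  tab <- generate_puncta_table(default_puncta_spec(seed = 30))
  base <- colocalization_summary(tab)
  shuf <- tab[sample(nrow(tab)), ]
  expect_equal(colocalization_summary(shuf)$mean_pct, base$mean_pct)
  # merge each neuron's segments into one row
  merged <- aggregate(cbind(n_psd, n_apposed) ~ neuron_id + animal_id + group,
                      data = tab, FUN = sum)
  merged$compartment <- "unspecified"; merged$segment_id <- 1
  m <- colocalization_summary(merged)
  expect_equal(m[order(m$group), ]$mean_pct,
               base[order(base$group), ]$mean_pct)
})

test_that("zero-PSD neurons are excluded with a warning", {
  tab <- data.frame(neuron_id = c("n1", "n2"), animal_id = "m1", group = "g",
                    compartment = "unspecified", segment_id = 1,
                    n_psd = c(0, 10), n_apposed = c(0, 5))
  expect_warning(s <- colocalization_summary(tab), "zero PSD")
  expect_equal(s$n_neurons, 1)
  expect_equal(s$mean_pct, 50)
})

test_that("background-corrected SF matches the measured arithmetic", {
  expect_equal(background_corrected_sf(50.61, 8.86), 0.4175)
  expect_equal(round(background_corrected_sf(50.61, 8.86), 2), 0.42)
  expect_equal(background_corrected_sf(36.13, 0), 0.3613)
  expect_equal(background_corrected_sf(10, 10), 0)
  expect_warning(sf <- background_corrected_sf(5, 10), "clamping")
  expect_equal(sf, 0)
  expect_error(background_corrected_sf(120, 5), "mean_with_oG_pct")
})

test_that("rank_sum_test exact branch matches hand enumeration", {
  t1 <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_true(t1$exact)
  expect_equal(t1$p.value, 0.1)   # 2/20 assignments as extreme
  expect_equal(t1$statistic, 6)
  t2 <- rank_sum_test(c(1.5, 2.5), c(1.5, 2.5))
  expect_false(t2$exact)          # ties force the approximation
  expect_equal(t2$p.value, 1)
  expect_error(rank_sum_test(numeric(0), 1:3), "nonempty")
})

test_that("exact p-values agree with the full enumeration oracle to 1e-12", {
  set.seed(19)
  for (i in 1:8) {
    a <- rnorm(9); b <- rnorm(9, mean = runif(1, 0, 1.5))
    mine <- rank_sum_test(a, b)
    expect_true(mine$exact)
    expect_equal(mine$p.value, rank_sum_enum_p(a, b), tolerance = 1e-12)
  }
  # unequal sizes too
  a <- rnorm(5); b <- rnorm(9)
  expect_equal(rank_sum_test(a, b)$p.value, rank_sum_enum_p(a, b),
               tolerance = 1e-12)
})

test_that("both branches agree with the reference implementation", {
  set.seed(23)
  for (i in 1:5) {
    a <- rnorm(8); b <- rnorm(10, 0.4)
    expect_equal(rank_sum_test(a, b)$p.value,
                 suppressWarnings(stats::wilcox.test(a, b, exact = TRUE)$p.value),
                 tolerance = 1e-12)
  }
  for (i in 1:5) {
    a <- rnorm(15); b <- rnorm(12, 0.3)
    expect_equal(rank_sum_test(a, b)$p.value,
                 stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-10)
    # tied data exercise the tie correction
    at <- round(rnorm(12), 1); bt <- round(rnorm(12, 0.3), 1)
    expect_equal(rank_sum_test(at, bt)$p.value,
                 stats::wilcox.test(at, bt, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("summary JSON includes groups and test results", {
  tab <- generate_puncta_table(default_puncta_spec(seed = 2))
  s <- colocalization_summary(tab)
  pn <- attr(s, "per_neuron")
  tst <- rank_sum_test(pn$fraction[pn$group == "oG"],
                       pn$fraction[pn$group == "no_oG"])
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_summary_json(s, path, tests = list(oG_vs_no_oG = tst))
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(back$groups), 2)
  expect_equal(back$tests$oG_vs_no_oG$p_value, tst$p.value)
})
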