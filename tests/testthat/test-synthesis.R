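test_that("aggregate size distribution hits both measured anchors", {
  d <- aggregate_size_distribution()
  expect_equal(d$params$p, 1 - 0.07^(1 / 6), tolerance = 1e-12)
  expect_equal(sum(d$prob[d$n < 7]), 0.93, tolerance = 1e-6)
  expect_gte(sum(d$prob[d$n < 15]), 0.99 - 0.01)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  # p -> 1 degenerates onto single beads
  d1 <- aggregate_size_distribution(p = 1 - 1e-12)
  expect_equal(d1$prob[1], 1, tolerance = 1e-9)
  expect_error(aggregate_size_distribution(anchor_lt7 = 1.2), "calibration")
})

test_that("beads-per-cell distribution matches the labeling anchors", {
  d <- beads_per_cell_distribution()
  expect_equal(d$mean, 50, tolerance = 0.5 / 50)
  expect_equal(sum(d$prob[d$n > 7]), 0.98, tolerance = 0.005 / 0.98)
  # infinite dispersion is Poisson
  dp <- beads_per_cell_distribution(mean = 50, dispersion = Inf)
  expect_equal(dp$prob[1:100], dpois(0:99, 50), tolerance = 1e-10)
  expect_error(beads_per_cell_distribution(anchor_gt7 = 0), "calibration")
})

test_that("sampled sizes agree with the probability tables (KS < 0.02)", {
  ks_table <- function(dist, draws) {
    emp <- cumsum(tabulate(match(draws, dist$n), length(dist$n))) / length(draws)
    max(abs(emp - cumsum(dist$prob)))
  }
  set.seed(101)
  da <- aggregate_size_distribution()
  expect_lt(ks_table(da, draw_sizes(da, 1e4)), 0.02)
  dc <- beads_per_cell_distribution()
  expect_lt(ks_table(dc, draw_sizes(dc, 1e4)), 0.02)
})

test_that("cells carry surface beads tilted to the operating magnetization", {
  b <- default_bead()
  set.seed(5)
  cell <- make_object("cell", 10, b, cell_diameter = 6e-6)
  expect_equal(sqrt(rowSums(cell$offsets^2)), rep(3e-6, 10), tolerance = 1e-12)
  set.seed(6)
  cell2 <- make_object("cell", 10, b)
  expect_false(isTRUE(all.equal(cell$offsets, cell2$offsets)))
  expect_identical(cell2$n_beads, 10L)
  # Monte-Carlo over many beads: mean vertical moment projection matches
  # the operating/saturation ratio within 2%
  set.seed(7)
  big <- make_object("cell", 1e4, b)
  expect_equal(mean(cos(big$theta)),
               b$moment_operating / b$moment_saturation, tolerance = 0.02)
  agg <- make_object("aggregate", 4, b)
  expect_true(all(agg$offsets == 0))
  expect_true(all(agg$theta == 0))
  expect_error(make_object("aggregate", 0, b), "at least 1")
})

test_that("generated samples follow the composition and the channel", {
  ch <- default_channel()
  neg <- sample_composition(cells_per_mL = 0, beads_per_mL = 2e5)
  ev <- generate_sample(neg, ch, 60, seed = 1)
  expect_false(any(ev$kind == "cell"))
  expect_true(all(ev$height_m >= ch$spacer &
                    ev$height_m <= ch$spacer + ch$height))
  expect_true(all(ev$t_arrival_s >= 0 & ev$t_arrival_s <= 60))
  # determinism: same seed, identical stream
  ev2 <- generate_sample(neg, ch, 60, seed = 1)
  expect_identical(ev[setdiff(names(ev), "object")],
                   ev2[setdiff(names(ev2), "object")])
})

test_that("arrival counts are Poisson in concentration times volume", {
  ch <- default_channel()
  comp <- sample_composition(cells_per_mL = 1e5, beads_per_mL = 0)
  # 1 mL equivalent: 30 min of flow
  counts <- vapply(1:20, function(s) {
    ev <- generate_sample(comp, ch, 1800, seed = s, materialize = "none")
    sum(ev$kind == "cell")
  }, numeric(1))
  lambda <- 1e5 * attr(generate_sample(comp, ch, 1800, seed = 1,
                                       materialize = "none"), "volume_mL")
  expect_equal(lambda, 1e5, tolerance = 1e-9)
  se <- sqrt(lambda / 20)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
  # unlabeled cells are dropped: all cell events carry at least one bead
  expect_true(all(vapply(1:3, function(s) {
    ev <- generate_sample(comp, ch, 60, seed = s, materialize = "none")
    all(ev$n_beads >= 1)
  }, logical(1))))
})

test_that("event counts scale linearly with concentration and duration", {
  ch <- default_channel()
  mean_count <- function(conc, dur) {
    mean(vapply(1:10, function(s) nrow(
      generate_sample(sample_composition(cells_per_mL = conc, beads_per_mL = 0),
                      ch, dur, seed = 100 + s, materialize = "none")),
      numeric(1)))
  }
  base <- mean_count(2e5, 90)
  expect_equal(mean_count(4e5, 90) / base, 2, tolerance = 0.15)
  expect_equal(mean_count(2e5, 180) / base, 2, tolerance = 0.15)
})

test_that("sample manifests round-trip through TSV", {
  ch <- default_channel()
  comp <- sample_composition(cells_per_mL = 5e4, beads_per_mL = 5e5)
  ev <- generate_sample(comp, ch, 30, seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_sample_manifest(ev, path)
  back <- read_sample_manifest(path)
  expect_equal(nrow(back), nrow(ev))
  expect_equal(back$n_beads, ev$n_beads)
  expect_equal(back$height_um, ev$height_m * 1e6, tolerance = 1e-5)
})
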