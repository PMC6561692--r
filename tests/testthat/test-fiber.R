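# one shared synthetic section for the quantification tests
sec <- gen_section(tpl_hemi, n_fibers = 30, contrast = 40, noise_sd = 5,
                   seed = 42)

test_that("quantification recovers planted per-line counts and conserves panels", {
  q <- quantify_section(sec$image, grid_hemi, h = 20)
  expect_equal(q$per_line, sec$truth$per_line)
  expect_equal(sum(q$raw_counts), sum(q$per_line))
  # detected event positions sit within a pixel or two of the analytic
  # crossing, so a crossing hugging a panel boundary may be booked to the
  # neighboring panel; totals are conserved and flips are rare
  flips <- sum(abs(q$raw_counts - sec$truth$per_panel)) / 2
  expect_lte(flips, 0.05 * sum(sec$truth$per_panel))
})

test_that("a fiberless section quantifies to an all-zero map", {
  s0 <- gen_section(tpl_hemi, n_fibers = 0, contrast = 40, noise_sd = 5,
                    seed = 1)
  q <- quantify_section(s0$image, grid_hemi, h = 20)
  expect_true(all(q$per_line == 0))
  expect_true(all(q$raw_counts == 0))
})

test_that("counts are invariant to affine intensity rescaling with relative h", {
  q1 <- quantify_section(sec$image, grid_hemi, h_frac = 0.25)
  img2 <- sec$image
  img2$data <- 1.7 * img2$data + 31
  q2 <- quantify_section(img2, grid_hemi, h_frac = 0.25)
  expect_identical(q1$per_line, q2$per_line)
  expect_identical(q1$raw_counts, q2$raw_counts)
})

test_that("adding a fiber never decreases any line count", {
  paths <- list(rbind(c(30, 830), c(450, 850)),
                rbind(c(205, 1305), c(505, 905)))
  extra <- rbind(c(95, 615), c(755, 585))
  s1 <- gen_section(tpl_hemi, contrast = 40, noise_sd = 0, seed = 2,
                    paths = paths)
  s2 <- gen_section(tpl_hemi, contrast = 40, noise_sd = 0, seed = 2,
                    paths = c(paths, list(extra)))
  expect_true(all(s2$truth$per_line >= s1$truth$per_line))
  q1 <- quantify_section(s1$image, grid_hemi, h = 20)
  q2 <- quantify_section(s2$image, grid_hemi, h = 20)
  expect_true(all(q2$per_line >= q1$per_line))
})

test_that("unregistered images are refused", {
  img <- sec$image
  img$frame <- "source"
  expect_error(quantify_section(img, grid_hemi, h = 20), "not registered")
  expect_error(midline_crossings(img, tpl_hemi, h = 20), "not registered")
})

test_that("normalization factor is the animal-to-cohort gray ratio", {
  expect_equal(normalization_factor(c(100, 110, 90), 100), 1.0)
  expect_equal(normalization_factor(200, 100), 2.0)
  cohort <- c(80, 100, 120)
  expect_equal(normalization_factor(cohort, cohort), 1.0)
  expect_error(normalization_factor(100, 0), "positive")
  m <- fiber_count_map(matrix(4, 20, 20), norm_factor = 2)
  expect_true(all(m$normalized_counts == 2))
  expect_error(fiber_count_map(matrix(-1, 20, 20)), "non-negative")
  expect_error(fiber_count_map(matrix(1, 20, 20), 0), "positive")
})

test_that("laminar sums conserve the map total", {
  q <- quantify_section(sec$image, grid_hemi, h = 20)
  m <- fiber_count_map(q, norm_factor = 1.3)
  ls <- laminar_sums(m, tpl_hemi, grid_hemi)
  expect_equal(sum(ls), sum(m$normalized_counts))
  expect_named(ls, c("I-III", "IV-V", "VI-VII", "VIII-IX", "X", "extra-GM"))
  # a map concentrated in one panel lands entirely in that panel's lamina
  one <- matrix(0, 20, 20); one[10, 3] <- 7
  ls1 <- laminar_sums(one, tpl_hemi, grid_hemi)
  expect_equal(sum(ls1 > 0), 1)
  expect_equal(sum(ls1), 7)
})

test_that("a uniform map splits evenly over a 50/50 laminar partition", {
  toy <- toy_rect_template(2000, 2000)
  g <- build_grid(toy)
  ls <- laminar_sums(matrix(1, 20, 20), toy, g)
  expect_equal(unname(ls[c("dorsal-half", "ventral-half")]), c(200, 200))
  expect_equal(unname(ls["extra-GM"]), 0)
})

test_that("midline crossings are binned to ~200 um from ~100 um windows", {
  s <- gen_section(tpl_hemi, n_fibers = 40, contrast = 40, noise_sd = 5,
                   seed = 13)
  mb <- midline_crossings(s$image, tpl_hemi, h = 20)
  truth_bins <- hist(s$truth$midline_positions_um,
                     breaks = seq(0, 1600, by = 200), plot = FALSE)$counts
  expect_equal(mb$count, truth_bins)
  # each bin is the sum of exactly two sampling windows
  wins <- attr(mb, "window_counts")
  expect_equal(mb$count, as.integer(tapply(wins, (seq_along(wins) - 1) %/% 2,
                                           sum)))
  expect_equal(sum(mb$count), length(s$truth$midline_positions_um))
  # bins are contiguous and non-overlapping
  expect_equal(mb$bin_start_um[-1], mb$bin_end_um[-nrow(mb)])
  # no fibers -> empty bins
  s0 <- gen_section(tpl_hemi, n_fibers = 0, contrast = 40, noise_sd = 5,
                    seed = 2)
  expect_true(all(midline_crossings(s0$image, tpl_hemi, h = 20)$count == 0))
})

test_that("group heat maps and difference maps obey their arithmetic", {
  m1 <- fiber_count_map(matrix(0, 20, 20))
  m2 <- fiber_count_map(matrix(2, 20, 20))
  hm <- group_heatmap(list(m1, m2))
  expect_true(all(hm == 1))
  expect_true(all(group_heatmap(list(m2, m2)) == m2$normalized_counts))
  expect_true(all(difference_map(hm, hm) == 0))
  expect_true(all(difference_map(hm, matrix(0, 20, 20)) == hm))
  expect_error(group_heatmap(list()), "non-empty")
})

test_that("per-line and panel outputs round-trip through CSV", {
  q <- quantify_section(sec$image, grid_hemi, h = 20)
  fl <- tempfile(fileext = ".csv"); fp <- tempfile(fileext = ".csv")
  write_fiber_counts(q, fl, fp)
  pl <- read.csv(fl)
  expect_equal(pl$count, unname(as.integer(q$per_line)))
  pp <- read.csv(fp)
  expect_equal(sum(pp$count), sum(q$raw_counts))
})
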