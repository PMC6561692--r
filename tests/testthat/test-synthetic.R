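test_that("an empty section is background plus noise with all-zero truth", {
  s <- gen_section(tpl_hemi, n_fibers = 0, contrast = 40, noise_sd = 2,
                   seed = 4)
  expect_true(all(s$truth$per_line == 0))
  expect_true(all(s$truth$per_panel == 0))
  expect_length(s$truth$midline_positions_um, 0)
  expect_lt(abs(mean(s$image$data) - 200), 1)
  expect_lt(abs(sd(as.vector(s$image$data)) - 2), 0.2)
})

test_that("a straight fiber crossing 7 vertical lines is recorded on exactly those", {
  # grid verticals at x = 0, 60, ..., 1140; the segment spans x in (30, 450)
  path <- rbind(c(30, 830), c(450, 850))
  s <- gen_section(tpl_hemi, contrast = 40, noise_sd = 0, seed = 1,
                   paths = list(path))
  hit <- paste0("v", 2:8)                      # x = 60 .. 420
  expect_true(all(s$truth$per_line[hit] == 1))
  expect_true(all(s$truth$per_line[setdiff(names(s$truth$per_line), hit)] == 0))
  # analytic oracle agrees line by line
  expect_equal(unname(s$truth$per_line),
               unname(truth_counts_oracle(list(path), grid_hemi)))
})

test_that("equal seeds give bit-identical images and ground truth", {
  a <- gen_section(tpl_hemi, n_fibers = 12, contrast = 40, noise_sd = 5,
                   seed = 77)
  b <- gen_section(tpl_hemi, n_fibers = 12, contrast = 40, noise_sd = 5,
                   seed = 77)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$truth, b$truth)
})

test_that("random-section ground truth equals brute-force segment enumeration", {
  for (sd in c(21, 22)) {
    s <- gen_section(tpl_hemi, n_fibers = 25, contrast = 40, noise_sd = 5,
                     seed = sd)
    expect_equal(unname(s$truth$per_line),
                 unname(truth_counts_oracle(s$truth$fiber_paths, grid_hemi)))
    # planted crossings on a line keep at least the 3 px separation floor
    ev <- s$truth$events
    for (lr in unique(ev$line_row)) {
      pos <- sort(ev$pos_um[ev$line_row == lr])
      if (length(pos) > 1)
        expect_gte(min(diff(pos)), 3 * tpl_hemi$pixel_size_um)
    }
    # panel assembly conserves the line totals
    expect_equal(sum(s$truth$per_panel), sum(s$truth$per_line))
  }
})

test_that("microglia fields carry exact planted parameters", {
  mg <- gen_microglia_field(tpl_hemi, n_cells = 1, index_range = c(1, 1),
                            soma_range_um = c(10, 10), seed = 3)
  expect_equal(mg$cells$activation_index, 1.0)
  expect_equal(mg$cells$longest_process_um, 10)
  mg2 <- gen_microglia_field(tpl_hemi, n_cells = 30, seed = 9)
  expect_true(all(point_in_gm(tpl_hemi, mg2$cells$x_um, mg2$cells$y_um)))
  expect_true(all(mg2$cells$activation_index >= 0.5 &
                  mg2$cells$activation_index <= 4))
  # measured-from-truth index equals the planted ratio exactly
  expect_equal(activation_index(mg2$cells$longest_process_um,
                                mg2$cells$soma_diameter_um),
               mg2$cells$activation_index)
  mg3 <- gen_microglia_field(tpl_hemi, n_cells = 30, seed = 9)
  expect_identical(mg2$cells, mg3$cells)
})

test_that("impossible cell packings raise a placement error", {
  tiny <- toy_rect_template(60, 60)
  expect_error(gen_microglia_field(tiny, n_cells = 200, seed = 1,
                                   max_tries = 20), "placement")
})

test_that("count simulation plants patterns with the stated NB moments", {
  des <- plant_design(n_genes = 400, n_per_group = 5, baseline_mean = 200,
                      dispersion = 0.1,
                      planted = list(list(pattern = "late-up", n = 20,
                                          lfc = 2)))
  a <- gen_counts(des, seed = 10)
  b <- gen_counts(des, seed = 10)
  expect_identical(a$counts, b$counts)
  expect_equal(sum(a$truth$planted), 20)
  # null genes pooled: variance within 10% of mu + phi mu^2 over >= 1e4 draws
  null_draws <- as.vector(a$counts[-(1:20), ])
  expect_gte(length(null_draws), 1e4)
  expect_lt(abs(var(null_draws) / (200 + 0.1 * 200^2) - 1), 0.1)
  # dispersion -> 0 limit is Poisson-like (variance ~ mean)
  des0 <- plant_design(n_genes = 400, n_per_group = 5, baseline_mean = 200,
                       dispersion = 1e-8, planted = list())
  c0 <- gen_counts(des0, seed = 11)
  expect_lt(abs(var(as.vector(c0$counts)) / 200 - 1), 0.1)
  # zero effect size is indistinguishable from the null stream
  des_null <- plant_design(n_genes = 400, n_per_group = 5,
                           baseline_mean = 200, dispersion = 0.1,
                           planted = list(list(pattern = "late-up", n = 20,
                                               lfc = 0)))
  des_none <- plant_design(n_genes = 400, n_per_group = 5,
                           baseline_mean = 200, dispersion = 0.1,
                           planted = list())
  expect_identical(gen_counts(des_null, seed = 5)$counts,
                   gen_counts(des_none, seed = 5)$counts)
})

test_that("planted patterns shift the intended groups only", {
  des <- plant_design(n_genes = 40, n_per_group = 200, baseline_mean = 500,
                      dispersion = 0.05,
                      planted = list(
                        list(pattern = "late-up", n = 10, lfc = 1),
                        list(pattern = "early-up", n = 10, lfc = 1),
                        list(pattern = "persistent-down", n = 10, lfc = 1)))
  sim <- gen_counts(des, seed = 2)
  gm <- t(apply(sim$counts, 1, tapply, sim$groups, mean))
  late_up <- colMeans(gm[1:10, ]) / 500
  expect_equal(unname(late_up[c("sham", "4", "7", "14")]),
               rep(1, 4), tolerance = 0.05)
  expect_equal(unname(late_up[c("28", "42")]), rep(2, 2), tolerance = 0.05)
  early_up <- colMeans(gm[11:20, ]) / 500
  expect_equal(unname(early_up[c("4", "7")]), rep(2, 2), tolerance = 0.05)
  pd <- colMeans(gm[21:30, ]) / 500
  expect_equal(unname(pd[c("4", "7", "14", "28", "42")]),
               rep(0.5, 5), tolerance = 0.05)
  expect_equal(unname(pd["sham"]), 1, tolerance = 0.05)
})

test_that("invalid designs are rejected", {
  expect_error(plant_design(dispersion = 0), "positive")
  expect_error(plant_design(planted = list(list(pattern = "late-up",
                                                n = 10, lfc = Inf))),
               "finite")
  expect_error(plant_design(n_genes = 10), "more planted")
  expect_error(gen_section(tpl_hemi, n_fibers = -1), ">= 0")
  expect_error(gen_section(tpl_hemi, contrast = 0), "positive")
})
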