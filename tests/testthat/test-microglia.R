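masks_hemi <- region_masks(tpl_hemi)

test_that("activation index is the exact process-to-soma ratio", {
  expect_equal(activation_index(10, 10), 1.0)
  expect_equal(activation_index(30, 10), 3.0)
  expect_equal(activation_index(0, 8), 0.0)
  expect_equal(activation_index(c(5, 12), c(10, 8)), c(0.5, 1.5))
  expect_error(activation_index(10, 0), "positive")
  expect_error(activation_index(-1, 10), "non-negative")
})

test_that("region priority is CST > CPA > VH > DH > GM-other", {
  # a CPA covering the whole frame exercises the overlap rules
  cpa <- matrix(TRUE, nrow(masks_hemi$GM), ncol(masks_hemi$GM))
  masks_cpa <- region_masks(tpl_hemi, cpa = cpa)
  cells <- data.frame(
    x_um = c(100, 300, 600, 300, -150),
    y_um = c(-150, 1300, 900, 200, 900),   # CST, VH(+CPA), mid-GM, DH, out
    soma_diameter_um = 10, longest_process_um = 15)
  rec <- suppressWarnings(classify_regions(cells, masks_cpa))
  expect_equal(rec$region, c("CST", "CPA", "CPA", "CPA"))
  expect_equal(nrow(attr(rec, "excluded")), 1)
  # without a CPA, the horn masks take over
  rec2 <- suppressWarnings(classify_regions(cells, masks_hemi))
  expect_equal(rec2$region, c("CST", "VH", "GM-other", "DH"))
  expect_equal(rec2$activation_index, rep(1.5, 4))
  expect_warning(classify_regions(cells, masks_hemi), "outside")
})

test_that("semirandom selection returns n_target distinct in-GM cells deterministically", {
  cells <- uniform_gm_cells(tpl_hemi, 300, seed = 3)
  sel <- semirandom_sample(cells, masks_hemi, n_target = 20, seed = 5)
  expect_equal(nrow(sel), 20)
  expect_equal(anyDuplicated(rownames(sel)), 0)
  expect_true(all(point_in_gm(tpl_hemi, sel$x_um, sel$y_um)))
  expect_identical(sel,
                   semirandom_sample(cells, masks_hemi, n_target = 20,
                                     seed = 5))
  # a different seed gives a different selection
  sel2 <- semirandom_sample(cells, masks_hemi, n_target = 20, seed = 6)
  expect_false(identical(rownames(sel), rownames(sel2)))
})

test_that("exactly n_target cells in GM are all returned, shrinking as needed", {
  cells20 <- uniform_gm_cells(tpl_hemi, 20, seed = 12)
  for (sd in 1:3) {
    sel <- semirandom_sample(cells20, masks_hemi, n_target = 20, seed = sd)
    expect_setequal(rownames(sel), rownames(cells20))
  }
  expect_error(semirandom_sample(cells20[1:10, ], masks_hemi,
                                 n_target = 20, seed = 1), "insufficient")
})

test_that("selection spreads over all four GM quadrants", {
  toy <- toy_rect_template(1200, 1600)
  masks <- region_masks(toy)
  set.seed(41)
  cells <- data.frame(x_um = runif(1000, 0, 1200),
                      y_um = runif(1000, 0, 1600))
  hits <- vapply(1:20, function(sd) {
    s <- semirandom_sample(cells, masks, 20, seed = sd)
    quadrants_covered(s$x_um, s$y_um, c(0, 1200), c(0, 1600))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("CPA level set matches the analytic Gaussian radius", {
  ps <- 5; s_um <- 150; sigma_um <- 20
  xy <- expand.grid(r = 1:200, c = 1:200)
  blob <- matrix(exp(-(((xy$c - 100)^2 + (xy$r - 100)^2) * ps^2) /
                       (2 * s_um^2)), 200, 200)
  cpa <- define_cpa(blob, frac = 0.8, smoothing_sigma_um = sigma_um,
                    pixel_size_um = ps)
  r_meas <- sqrt(sum(cpa) / pi)
  r_theory <- sqrt(2 * (s_um^2 + sigma_um^2) * log(1 / 0.8)) / ps
  expect_lt(abs(r_meas - r_theory), 1)
  # area is non-increasing in frac, and frac -> 1 shrinks to the peak
  areas <- vapply(c(0.5, 0.7, 0.9, 0.99),
                  function(f) sum(define_cpa(blob, f, sigma_um,
                                             pixel_size_um = ps)),
                  numeric(1))
  expect_true(all(diff(areas) < 0))
  tiny <- define_cpa(blob, 0.999, sigma_um, pixel_size_um = ps)
  expect_true(tiny[100, 100])
  expect_lt(sum(tiny), 30)
})

test_that("CPA keeps only the component containing the global maximum", {
  m <- matrix(0, 120, 120)
  xy <- expand.grid(r = 1:120, c = 1:120)
  m <- m + matrix(exp(-((xy$r - 30)^2 + (xy$c - 30)^2) / 50), 120, 120)
  m <- m + matrix(0.999 * exp(-((xy$r - 90)^2 + (xy$c - 90)^2) / 50),
                  120, 120)
  cpa <- define_cpa(m, frac = 0.8, smoothing_sigma_um = 0,
                    pixel_size_um = 1)
  expect_true(cpa[30, 30])
  expect_false(cpa[90, 90])
  expect_error(define_cpa(matrix(1, 50, 50), 0.8, pixel_size_um = 1),
               "constant")
  expect_error(define_cpa(m, frac = 1, pixel_size_um = 1), "in \\(0, 1\\)")
})

test_that("activation and density maps aggregate and fold correctly", {
  mg <- gen_microglia_field(tpl_hemi, n_cells = 40, seed = 21)
  rec <- classify_regions(mg$cells, masks_hemi)
  rec$group <- rep(c("sham", "stroke"), length.out = nrow(rec))
  maps <- activation_maps(rec, grid_hemi)
  # density conservation: panel sums equal classified in-grid cells
  expect_equal(sum(maps$density$sham) + sum(maps$density$stroke), nrow(rec))
  # identical group and sham maps give fold change 1 wherever defined
  rec2 <- rec; rec2$group <- "sham"
  rec3 <- rec; rec3$group <- "stroke"
  both <- rbind(rec2, rec3)
  m2 <- activation_maps(both, grid_hemi)
  fa <- m2$activation_fold$stroke
  expect_true(all(fa[!is.na(fa)] == 1))
  fd <- m2$density_fold$stroke
  expect_true(all(fd[!is.na(fd)] == 1))
  # sham-empty panels are missing, not infinite
  expect_true(all(is.na(maps$density_fold$stroke[maps$density$sham == 0])))
  expect_false(any(is.infinite(maps$density_fold$stroke), na.rm = TRUE))
})

test_that("cell annotation tables convert pixel to physical coordinates", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(section_id = "s1", cell_id = 1:2, row = c(0, 9),
                       col = c(0, 19), soma_diameter_um = 10,
                       longest_process_um = 20), f, row.names = FALSE)
  cells <- read_cell_annotations(f, pixel_size_um = 2)
  expect_equal(cells$x_um, c(1, 39))
  expect_equal(cells$y_um, c(1, 19))
})
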