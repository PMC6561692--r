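make_em <- function(counts, groups, ...) {
  cpm_normalize(counts, groups, ...)
}

test_that("CPM normalization follows the per-million identity", {
  counts <- matrix(c(5, 0, 995e3,
                     10, 0, 99e4), 3, 2,
                   dimnames = list(c("a", "zero", "big"), c("s1", "s2")))
  em <- make_em(counts, c("sham", "4"), lib_sizes = c(1e6, 1e6))
  expect_equal(em$cpm["a", "s1"], 5)
  expect_true(all(em$cpm["zero", ] == 0))
  # column sums of CPM are 1e6 when library sizes are the column sums
  em2 <- make_em(counts, c("sham", "4"))
  expect_equal(unname(colSums(em2$cpm)), c(1e6, 1e6))
  expect_error(make_em(counts, c("sham", "4"), lib_sizes = c(0, 1)),
               "positive")
})

test_that("the low-expression filter drops mean CPM <= 5 (exclusive keep)", {
  counts <- rbind(at_5 = c(5, 5), just_above = c(5.01, 5.01),
                  high = c(100, 100))
  em <- make_em(counts, c("sham", "4"), lib_sizes = c(1e6, 1e6))
  kept <- filter_low_expression(em)
  expect_equal(rownames(kept$cpm), c("just_above", "high"))
  expect_equal(attr(kept, "n_dropped"), 1)
  # an empty result is allowed
  low <- make_em(rbind(g = c(1, 1)), c("sham", "4"),
                 lib_sizes = c(1e6, 1e6))
  expect_equal(nrow(filter_low_expression(low)$cpm), 0)
  # max aggregation keeps a gene that peaks in one sample
  peaky <- make_em(rbind(g = c(0, 12)), c("sham", "4"),
                   lib_sizes = c(1e6, 1e6))
  expect_equal(nrow(filter_low_expression(peaky)$cpm), 1)
  expect_equal(nrow(filter_low_expression(peaky, aggregate = "max")$cpm), 1)
})

test_that("fold changes use group-over-sham means with a 0.5 pseudocount", {
  counts <- rbind(flat = c(10, 10, 10, 10),
                  up4 = c(10, 10, 40, 40),
                  zero = c(0, 0, 0, 0))
  em <- make_em(counts, c("sham", "sham", "4", "4"),
                lib_sizes = rep(1e6, 4))
  fc <- fold_changes(em)
  expect_equal(unname(fc$fc["flat", "4"]), 1)
  expect_equal(unname(fc$log2_fc["up4", "4"]),
               log2(40.5 / 10.5))
  expect_equal(unname(fc$fc["zero", "4"]), 1)   # 0/0 -> 1 under pseudocount
  # approximate scale equivariance (exact as the pseudocount vanishes)
  em2 <- em; em2$cpm["up4", em$groups == "4"] <- 3 * em$cpm["up4", em$groups == "4"]
  fc2 <- fold_changes(em2, pseudocount = 1e-9)
  expect_equal(unname(fc2$fc["up4", "4"]), 12, tolerance = 1e-6)
  em_nosham <- make_em(counts, c("4", "4", "7", "7"))
  expect_error(fold_changes(em_nosham), "sham")
})

test_that("BH adjustment equals brute-force step-up enumeration", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_equal(bh_bruteforce(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(88)
  for (k in 1:200) {
    p <- runif(sample(1:8, 1))
    expect_equal(p.adjust(p, "BH"), bh_bruteforce(p))
  }
})

test_that("the Welch row test matches stats::t.test gene by gene", {
  set.seed(17)
  x1 <- matrix(rnorm(50, 5), 10, 5)
  x2 <- matrix(rnorm(50, 6), 10, 5)
  p_pkg <- cordmap:::row_welch(x1, x2)
  p_ref <- vapply(1:10, function(i)
    t.test(x1[i, ], x2[i, ])$p.value, numeric(1))
  expect_equal(p_pkg, p_ref, tolerance = 1e-12)
})

test_that("SDEG calling flags fdr < alpha AND |log2FC| >= 1.5, with fallback", {
  set.seed(23)
  counts <- matrix(rnbinom(200 * 10, mu = 200, size = 10), 200, 10,
                   dimnames = list(sprintf("g%03d", 1:200), NULL))
  counts[1, 6:10] <- counts[1, 6:10] * 8      # strong planted shift
  counts[2, ] <- c(rep(100, 5), rep(110, 5))  # zero-variance rows
  em <- make_em(counts, rep(c("sham", "28"), each = 5),
                lib_sizes = rep(1e6, 10))
  sdt <- call_sdegs(em, test = "welch")
  expect_true(sdt$sdeg_28[1])
  # degenerate variance fell back to the exact permutation test
  expect_equal(sdt$p_28[2], 2 / choose(10, 5), tolerance = 1e-3)
  # the SDEG flag is exactly the conjunction of its two gates
  expect_equal(sdt$sdeg_28,
               sdt$fdr_28 < 0.05 & abs(sdt$log2_fc_28) >= 1.5)
  expect_false(any(sdt$sdeg_28 & abs(sdt$log2_fc_28) < 1.5))
  # fdr respects the step-up ordering against raw p
  expect_true(all(sdt$fdr_28 >= sdt$p_28 - 1e-12))
  # moderated default agrees on the strong effect
  sdt_mod <- call_sdegs(em)
  expect_true(sdt_mod$sdeg_28[1])
})

test_that("SDEG calls are invariant to permuting samples within groups", {
  sim <- gen_counts(plant_design(n_genes = 300, planted = list(
    list(pattern = "late-up", n = 20, lfc = 2))), seed = 3)
  em <- make_em(sim$counts, sim$groups)
  perm <- seq_len(ncol(sim$counts))
  for (g in levels(sim$groups)) {
    i <- which(sim$groups == g)
    perm[i] <- sample(i)
  }
  em_p <- make_em(sim$counts[, perm], sim$groups[perm])
  a <- call_sdegs(em)
  b <- call_sdegs(em_p)
  expect_equal(a$sdeg, b$sdeg)
  expect_equal(a$fc_28, b$fc_28)
})

test_that("pattern clustering recovers planted temporal profiles", {
  groups <- c("sham", "4", "7", "14", "28", "42")
  centro <- rbind("persistent-down" = c(2, 0, 0, 0, 0, 0),
                  "late-up" = c(0, 0, 0, 0, 2, 2),
                  "late-down" = c(2, 2, 2, 2, 0, 0),
                  "early-up" = c(0, 2, 2, 0, 0, 0))
  colnames(centro) <- groups
  set.seed(6)
  prof <- centro[rep(1:4, each = 25), ] + rnorm(600, 0, 0.01)
  cl <- cluster_patterns(prof, k = 4)
  truth <- rep(rownames(centro), each = 25)
  expect_equal(mclust::adjustedRandIndex(cl$cluster, truth), 1)
  expect_equal(cl$pattern, truth)
  # a profile up only at 28/42 dpi is late-up by the labeling rule
  expect_equal(unique(cl$pattern[26:50]), "late-up")
})

test_that("clustering is invariant to gene order and rejects degenerate input", {
  groups <- c("sham", "4", "7", "14", "28", "42")
  set.seed(14)
  prof <- matrix(rnorm(240), 40, 6, dimnames = list(NULL, groups))
  cl <- cluster_patterns(prof, k = 4)
  perm <- sample(40)
  cl_p <- cluster_patterns(prof[perm, ], k = 4)
  expect_equal(mclust::adjustedRandIndex(cl$cluster[perm], cl_p$cluster), 1)
  expect_error(cluster_patterns(prof[1:3, ], k = 4), "fewer")
  flat <- matrix(rep(c(1, 2, 3, 4, 5, 6), each = 10), 10,
                 dimnames = list(NULL, groups))
  expect_error(cluster_patterns(flat, k = 4), "distinct")
  expect_error(cluster_patterns(matrix(3, 10, 6,
                                       dimnames = list(NULL, groups)),
                                k = 4), "constant")
})

test_that("count matrices round-trip with their sample sheets", {
  sim <- gen_counts(plant_design(n_genes = 50, planted = list(
    list(pattern = "late-up", n = 5, lfc = 2))), seed = 8)
  fc <- tempfile(fileext = ".tsv"); fs <- tempfile(fileext = ".csv")
  write.table(data.frame(gene = rownames(sim$counts), sim$counts,
                         check.names = FALSE),
              fc, sep = "\t", row.names = FALSE, quote = FALSE)
  write.csv(data.frame(sample = colnames(sim$counts),
                       group = as.character(sim$groups)),
            fs, row.names = FALSE)
  back <- read_count_matrix(fc, fs)
  expect_equal(unname(back$counts), unname(sim$counts))
  expect_equal(as.character(back$groups), as.character(sim$groups))
})
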